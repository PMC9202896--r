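#' Simulate one complete randomized trial
#'
#' Draws independent HWE genotypes, a balanced treatment allocation, a
#' generative model with the requested architecture and the resulting
#' quantitative trait; the workhorse behind the simulation studies.
#'
#' @param n,p cohort and panel sizes.
#' @param k number of causal SNPs (half prognostic, half predictive).
#' @param cEff effect-size multiplier.
#' @param mu overall treatment effect.
#' @param sigma error SD.
#' @param seed integer seed covering every draw in the trial.
#' @return list with elements \code{gs} ([StandardizedGenotypes-class]),
#'   \code{design} ([TrialDesign-class]), \code{model}
#'   ([TrueModel-class]), \code{y} (outcome), \code{rTrue} (true
#'   predictive index).
#' @export
simulateTrial <- function(n = 1000, p = 100, k = 10, cEff = 1.5, mu = 0,
                          sigma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulateGenotypes(n, p)
  gs <- standardizeGenotypes(g)
  tr <- simulateTreatment(n)
  design <- buildDesign(gs, tr)
  model <- makeTrueModel(p, k = k, cEff = cEff, mu = mu, sigma = sigma)
  y <- simulateTrait(design, model)
  list(gs = gs, design = design, model = model, y = y,
       rTrue = truePredictiveIndex(model, gs))
}

# Run one named selector on a simulated trial; returns a SelectionResult.
.runSelector <- function(method, design, y, mEff = NULL, seed = NULL) {
  m <- ncol(design@values)
  p <- m %/% 2L
  switch(method,
    bonferroni = {
      pv <- marginalTests(design, y)
      .finalizeSelection(design, y,
        bonferroniSelect(pv, 0.05, if (is.null(mEff)) m else mEff),
        "bonferroni")
    },
    bh = {
      pv <- marginalTests(design, y)
      .finalizeSelection(design, y,
        bhSelect(pv, 0.05, if (is.null(mEff)) m else mEff), "bh")
    },
    mbic2 = mbic2Search(design, y, mCandidates = mEff),
    slobe = slobe(design, y, q = 0.05, seed = seed),
    adalasso = adaptiveLasso(design, y, seed = seed),
    ols = {
      if (m + 2 >= nrow(design@values))
        stop("full OLS baseline needs 2p + 2 < n")
      fitSelectedModel(design, y, seq_len(p), seq_len(p), "ols")
    },
    stop("unknown method: ", method))
}

# Metrics of one fitted selection against the truth, as tidy rows.
.replicateMetrics <- function(trial, sel, clusters = NULL,
                              tpDefinition = "strict") {
  sm <- selectionMetrics(trial$model, sel, clusters = clusters,
                         mode = tpDefinition)
  rhat <- predictedIndex(sel, trial$gs)
  rr <- responderRates(trial$rTrue, rhat)
  c(sm, mseIndex = mseIndex(trial$rTrue, rhat), rr)
}

#' Simulation study: biomarker identification with independent SNPs
#'
#' For each number of causal SNPs k and each selection method, simulates
#' \code{reps} independent randomized trials (n patients, p independent
#' HWE SNPs, effects \eqn{\pm c_{eff}\sqrt{2\log p}}, half prognostic /
#' half predictive, \eqn{\mu} overall effect) and records selection
#' power/FDR, the standardized MSE of the predictive index and responder
#' detection rates.
#'
#' @param p panel size (the reference settings are 100 and 2000).
#' @param kValues numbers of causal SNPs (default \code{c(2,6,10,30,50)}).
#' @param reps replicates per cell.
#' @param methods selectors to run; \code{"ols"} (the all-marker
#'   least-squares baseline) is kept only when 2p + 2 < n.
#' @param n cohort size.
#' @param cEff,mu,sigma generative parameters.
#' @param baseSeed replicate r of cell i uses seed
#'   \code{baseSeed + 1000*i + r}.
#' @return tidy data.frame with columns method, k, replicate, metric,
#'   value.
#' @seealso [aggregateMetrics()]
#' @export
runPart1 <- function(p = 100, kValues = c(2, 6, 10, 30, 50), reps = 200,
                     methods = c("bonferroni", "bh", "mbic2", "slobe",
                                 "adalasso"),
                     n = 1000, cEff = 1.5, mu = 0, sigma = 1,
                     baseSeed = 1) {
  if ("ols" %in% methods && 2 * p + 2 >= n) {
    methods <- setdiff(methods, "ols")
  }
  out <- vector("list", length(kValues) * reps * length(methods))
  slot <- 0L
  for (i in seq_along(kValues)) {
    k <- kValues[i]
    for (r in seq_len(reps)) {
      seed <- baseSeed + 1000L * i + r
      trial <- simulateTrial(n, p, k, cEff, mu, sigma, seed = seed)
      for (method in methods) {
        sel <- .runSelector(method, trial$design, trial$y, seed = seed)
        met <- .replicateMetrics(trial, sel)
        slot <- slot + 1L
        out[[slot]] <- data.frame(method = method, k = k, replicate = r,
                                  metric = names(met), value = unname(met))
      }
    }
  }
  do.call(rbind, out[seq_len(slot)])
}

#' Simulation study: correlated SNP panels and the p_eff substitution
#'
#' Uses one fixed genotype panel with LD clusters (a supplied
#' [SnpGenotypes-class] with cluster labels, or a synthetic
#' block-equicorrelated panel) and a fixed 15-SNP causal layout (5 purely
#' prognostic, 5 purely predictive, 5 both, spread over clusters of sizes
#' 1, 2, 3, 5 and >= 6). Per replicate a fresh treatment allocation and
#' trait are drawn and every method's selection is scored under the
#' strict and the cluster-relaxed true-positive definitions, including
#' per-SNP detection indicators. Bonferroni, BH and the mBIC2 penalty use
#' the effective number of markers when \code{usePEff} is TRUE.
#'
#' @param genotypes a [SnpGenotypes-class] with cluster labels, or NULL
#'   to simulate a synthetic block panel.
#' @param blockSizes,rho synthetic-panel shape (used when
#'   \code{genotypes} is NULL).
#' @param cEff effect-size multiplier.
#' @param reps replicates.
#' @param methods selectors to run.
#' @param n cohort size (used for the synthetic panel).
#' @param usePEff substitute the effective number of markers for the raw
#'   test count (default TRUE).
#' @param pEffB null replicates inside [effectiveNumberOfMarkers()].
#' @param baseSeed seed; replicate r uses \code{baseSeed + r}.
#' @return list with \code{metrics} (tidy per-replicate data.frame with a
#'   tpDefinition column), \code{perSnp} (per causal SNP detection
#'   frequencies by method and definition), \code{pEff}, \code{model},
#'   \code{layout}.
#' @export
runPart2 <- function(genotypes = NULL,
                     blockSizes = rep(c(1, 2, 3, 5, 8), 40), rho = 0.9,
                     cEff = 1.5, reps = 100,
                     methods = c("bonferroni", "bh", "mbic2"),
                     n = 1000, usePEff = TRUE, pEffB = 500, baseSeed = 1) {
  if (is.null(genotypes))
    genotypes <- simulateBlockGenotypes(n, blockSizes, rho,
                                        seed = baseSeed)
  if (is.null(clusterIds(genotypes)))
    stop("Part-2 genotypes must carry cluster labels")
  gs <- standardizeGenotypes(genotypes)
  clusters <- clusterIds(genotypes)
  p <- ncol(stdValues(gs))
  nS <- nrow(stdValues(gs))
  layout <- part2Layout(gs, seed = baseSeed)
  model <- makeTrueModel(p, cEff = cEff, mu = 0,
                         layoutType = "overlap15", layout = layout,
                         seed = baseSeed)
  causal <- sort(unique(c(model@iBeta, model@iGamma)))

  pEff <- NULL
  mEff <- NULL
  if (usePEff) {
    trRef <- simulateTreatment(nS, seed = baseSeed)
    dRef <- buildDesign(gs, trRef)
    pEff <- effectiveNumberOfMarkers(dRef, B = pEffB, seed = baseSeed)
    mEff <- pEff$pEff
  }

  metricRows <- list()
  hits <- array(0L,
    dim = c(length(methods), length(causal), 2L),
    dimnames = list(methods, paste0("snp", causal), c("strict", "cluster")))
  for (r in seq_len(reps)) {
    seed <- baseSeed + r
    set.seed(seed)
    tr <- simulateTreatment(nS)
    design <- buildDesign(gs, tr)
    y <- simulateTrait(design, model)
    rTrue <- truePredictiveIndex(model, gs)
    trial <- list(gs = gs, design = design, model = model, y = y,
                  rTrue = rTrue)
    for (method in methods) {
      sel <- .runSelector(method, design, y, mEff = mEff, seed = seed)
      selected <- sort(unique(c(sel@iBeta, sel@iGamma)))
      for (mode in c("strict", "cluster")) {
        met <- .replicateMetrics(trial, sel, clusters = clusters,
                                 tpDefinition = mode)
        metricRows[[length(metricRows) + 1L]] <-
          data.frame(method = method, tpDefinition = mode, replicate = r,
                     metric = names(met), value = unname(met))
        det <- if (mode == "strict") causal %in% selected
               else clusters[causal] %in% clusters[selected]
        hits[method, , mode] <- hits[method, , mode] + det
      }
    }
  }
  perSnp <- do.call(rbind, lapply(methods, function(mth) {
    do.call(rbind, lapply(c("strict", "cluster"), function(mode) {
      data.frame(method = mth, tpDefinition = mode, snp = causal,
                 clusterSize = as.integer(table(clusters)[
                   as.character(clusters[causal])]),
                 role = ifelse(causal %in% model@iBeta &
                               causal %in% model@iGamma, "both",
                        ifelse(causal %in% model@iBeta, "prognostic",
                               "predictive")),
                 detectionRate = hits[mth, , mode] / reps)
    }))
  }))
  list(metrics = do.call(rbind, metricRows), perSnp = perSnp,
       pEff = pEff, model = model, layout = layout)
}

#' Simulation study: power of the efficacy-testing strategies
#'
#' Runs the five testing strategies over the scenario grid (overall
#' treatment effect mu and marker effect multiplier cEff per scenario)
#' for each number of causal SNPs, and records per-replicate rejections.
#'
#' @param scenarios subset of 1:4; the reference grid is
#'   mu = 0, 0.07, 0.1, 0.12 paired with cEff = 1.5, 1.5, 1.3, 1.2.
#' @param kValues numbers of causal SNPs.
#' @param reps replicates per cell.
#' @param methods strategy labels among \code{"M1", "M2", "M2a", "M3",
#'   "M4"}.
#' @param n,p cohort and panel sizes (reference: 1000 and 500).
#' @param alpha nominal level.
#' @param baseSeed seed; the replicate seed is
#'   \code{baseSeed + 7919*scenario + 1000*kIndex + r}.
#' @return tidy data.frame with columns scenario, mu, cEff, k, method,
#'   replicate, reject.
#' @export
runPart3 <- function(scenarios = 1:4, kValues = c(2, 6, 10, 30, 50),
                     reps = 200, methods = c("M1", "M2", "M2a", "M3", "M4"),
                     n = 1000, p = 500, alpha = 0.05, baseSeed = 1) {
  grid <- data.frame(scenario = 1:4,
                     mu = c(0, 0.07, 0.1, 0.12),
                     cEff = c(1.5, 1.5, 1.3, 1.2))
  grid <- grid[grid$scenario %in% scenarios, , drop = FALSE]
  out <- list()
  for (s in seq_len(nrow(grid))) {
    sc <- grid[s, ]
    for (i in seq_along(kValues)) {
      k <- kValues[i]
      for (r in seq_len(reps)) {
        seed <- baseSeed + 7919L * sc$scenario + 1000L * i + r
        trial <- simulateTrial(n, p, k, sc$cEff, sc$mu, seed = seed)
        for (method in methods) {
          oc <- switch(method,
            M1 = efficacyMethod1(trial$y, trial$design@treatment, alpha),
            M2 = efficacyMethod2(trial$design, trial$y, alpha),
            M2a = efficacyMethod2a(trial$design, trial$y, alpha),
            M3 = efficacyMethod3(trial$design, trial$y, alpha,
                                 seed = seed),
            M4 = efficacyMethod4(trial$design, trial$y, alpha,
                                 seed = seed),
            stop("unknown method: ", method))
          out[[length(out) + 1L]] <-
            data.frame(scenario = sc$scenario, mu = sc$mu, cEff = sc$cEff,
                       k = k, method = method, replicate = r,
                       reject = oc@reject)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate tidy per-replicate metrics to means with Monte-Carlo SEs
#'
#' @param df a tidy data.frame from [runPart1()] or the metrics component
#'   of [runPart2()] (columns: grouping..., metric, value), or from
#'   [runPart3()] (grouping..., reject).
#' @return data.frame of group means and standard errors; NaN values
#'   (undefined rates) are dropped before averaging.
#' @export
aggregateMetrics <- function(df) {
  if ("reject" %in% names(df)) {
    groups <- setdiff(names(df), c("replicate", "reject"))
    agg <- stats::aggregate(df$reject,
                            by = df[groups], FUN = function(v)
                              c(mean = mean(v),
                                se = stats::sd(v) / sqrt(length(v))))
    res <- cbind(agg[groups], power = agg$x[, "mean"], se = agg$x[, "se"])
    return(res)
  }
  groups <- setdiff(names(df), c("replicate", "value"))
  keep <- !is.nan(df$value) & !is.na(df$value)
  df <- df[keep, , drop = FALSE]
  agg <- stats::aggregate(df$value,
                          by = df[groups], FUN = function(v)
                            c(mean = mean(v),
                              se = stats::sd(v) / sqrt(length(v))))
  cbind(agg[groups], mean = agg$x[, "mean"], se = agg$x[, "se"])
}
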