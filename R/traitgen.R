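#' Construct the generative truth for a simulated trial
#'
#' Draws causal SNP index sets and coefficients for the generating model
#' of [simulateTrait()]. Every nonzero coefficient has magnitude
#' \eqn{c_{eff}\sqrt{2\log p}} (natural log) with an independent
#' Rademacher sign.
#'
#' Layouts:
#' \describe{
#'   \item{\code{"split"}}{\code{k} causal SNPs drawn uniformly without
#'     replacement, half purely prognostic and half purely predictive
#'     (disjoint sets); \code{k} must be even. This is the architecture of
#'     the independent-SNP and efficacy simulations.}
#'   \item{\code{"overlap15"}}{15 causal SNPs: 5 purely prognostic, 5
#'     purely predictive and 5 both, used with correlated panels. Supply
#'     explicit indices via \code{layout} (a list with elements
#'     \code{prognostic}, \code{predictive}, \code{both}, each of length
#'     5) or leave \code{NULL} to sample them from distinct clusters when
#'     the genotypes carry cluster labels (see [part2Layout()]).}
#' }
#'
#' @param p total number of candidate SNPs.
#' @param k number of causal SNPs (layout \code{"split"}; even).
#' @param cEff effect-size multiplier, e.g. 1.5.
#' @param mu overall treatment effect.
#' @param sigma error SD (default 1).
#' @param layoutType \code{"split"} or \code{"overlap15"}.
#' @param layout explicit index sets for \code{"overlap15"} (see above).
#' @param seed integer seed.
#' @return a [TrueModel-class].
#' @export
makeTrueModel <- function(p, k = NULL, cEff = 1.5, mu = 0, sigma = 1,
                          layoutType = c("split", "overlap15"),
                          layout = NULL, seed = NULL) {
  layoutType <- match.arg(layoutType)
  if (!is.null(seed)) set.seed(seed)
  amp <- cEff * sqrt(2 * log(p))
  if (layoutType == "split") {
    if (is.null(k)) stop("k is required for the split layout")
    if (k %% 2 != 0) stop("k must be even: half prognostic, half predictive")
    if (k > p) stop("k must not exceed p")
    idx <- sample.int(p, k)
    iBeta <- sort(idx[seq_len(k / 2)])
    iGamma <- sort(idx[setdiff(seq_len(k), seq_len(k / 2))])
  } else {
    if (p < 15) stop("overlap15 layout needs p >= 15")
    if (is.null(layout)) {
      idx <- sample.int(p, 15)
      layout <- list(prognostic = idx[1:5], predictive = idx[6:10],
                     both = idx[11:15])
    }
    stopifnot(lengths(layout[c("prognostic", "predictive", "both")]) == 5)
    iBeta <- sort(c(layout$prognostic, layout$both))
    iGamma <- sort(c(layout$predictive, layout$both))
  }
  beta <- amp * sample(c(-1, 1), length(iBeta), replace = TRUE)
  gamma <- amp * sample(c(-1, 1), length(iGamma), replace = TRUE)
  new("TrueModel", p = as.integer(p),
      iBeta = as.integer(iBeta), iGamma = as.integer(iGamma),
      beta = beta, gamma = gamma,
      mu = mu, sigma = sigma, cEff = cEff)
}

#' Pick the 15-SNP causal layout from cluster labels
#'
#' For each causal group (purely prognostic, purely predictive, both) the
#' five SNPs are drawn from clusters whose sizes are closest to 1, 2, 3, 5
#' and >= 6, one SNP per cluster, with all fifteen clusters distinct.
#'
#' @param gs a genotype object carrying cluster labels
#'   ([SnpGenotypes-class] or [StandardizedGenotypes-class]).
#' @param seed integer seed.
#' @return list with integer elements \code{prognostic}, \code{predictive},
#'   \code{both}, each of length 5.
#' @export
part2Layout <- function(gs, seed = NULL) {
  cl <- clusterIds(gs)
  if (is.null(cl)) stop("genotypes carry no cluster labels")
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(cl)
  wanted <- c(1, 2, 3, 5, 6)
  used <- integer(0)
  pickCluster <- function(target) {
    avail <- setdiff(as.integer(names(sizes)), used)
    sz <- as.integer(sizes[as.character(avail)])
    ok <- if (target >= 6) avail[sz >= 6] else avail[sz == target]
    if (!length(ok)) { # fall back to the nearest available size
      ok <- avail[order(abs(sz - target))][1L]
    }
    cid <- if (length(ok) > 1) sample(ok, 1L) else ok
    used <<- c(used, cid)
    members <- which(cl == cid)
    if (length(members) > 1) sample(members, 1L) else members
  }
  pickGroup <- function() vapply(wanted, pickCluster, integer(1))
  list(prognostic = pickGroup(), predictive = pickGroup(),
       both = pickGroup())
}

#' Simulate a quantitative trait from the generative model
#'
#' Generates
#' \deqn{Y_i = \mu T_i + \sum_{j \in I_\beta} \beta_j X_{ij}
#'   + \sum_{j \in I_\gamma} \gamma_j X_{ij} T_i + \epsilon_i}
#' with i.i.d. Gaussian errors, where \eqn{X} is the standardized
#' genotype matrix inside \code{design}.
#'
#' @param design a [TrialDesign-class].
#' @param model a [TrueModel-class].
#' @param seed integer seed for the error draw.
#' @return numeric outcome vector of length n.
#' @export
simulateTrait <- function(design, model, seed = NULL) {
  stopifnot(is(design, "TrialDesign"), is(model, "TrueModel"))
  X <- design@values
  p <- ncol(X) %/% 2L
  if (model@p != p) stop("model and design disagree on p")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  y <- model@mu * design@treatment + stats::rnorm(n, 0, model@sigma)
  if (length(model@iBeta))
    y <- y + drop(X[, model@iBeta, drop = FALSE] %*% model@beta)
  if (length(model@iGamma))
    y <- y + drop(X[, p + model@iGamma, drop = FALSE] %*% model@gamma)
  y
}

#' Heritability of a simulated scenario
#'
#' Percentage of trait variance attributable to the genetic effects and to
#' the treatment under the split-layout generative model with unit-L2
#' standardized genotypes: each of the k causal markers contributes
#' variance \eqn{c_{eff}^2\, 2\log(p)/n} (its squared coefficient divided
#' by n, since columns have norm 1), the treatment contributes
#' \eqn{\mu^2}, and the error contributes \eqn{\sigma^2}.
#'
#' @param n,p,k scenario dimensions.
#' @param cEff effect-size multiplier.
#' @param mu overall treatment effect.
#' @param sigma error SD (default 1).
#' @param digits rounding of the reported percentages (default 1, the
#'   conventional reporting precision).
#' @return named numeric vector \code{c(hGen = ..., hTrt = ...)} in
#'   percent.
#' @examples
#' heritability(n = 1000, p = 500, k = 2, cEff = 1.5, mu = 0)
#' @export
heritability <- function(n, p, k, cEff, mu, sigma = 1, digits = 1) {
  varGen <- k * cEff^2 * 2 * log(p) / n
  varTrt <- mu^2
  tot <- sigma^2 + varGen + varTrt
  c(hGen = round(100 * varGen / tot, digits),
    hTrt = round(100 * varTrt / tot, digits))
}

#' True predictive index (predicted individual treatment effect)
#'
#' The expected benefit of treatment over control for a patient with
#' standardized genotype row x:
#' \deqn{R(x) = E[Y\,|\,x, T{=}1] - E[Y\,|\,x, T{=}{-1}]
#'   = 2\big(\mu + \sum_{j \in I_\gamma} \gamma_j x_j\big).}
#' A patient is a responder when R(x) > 0.
#'
#' @param model a [TrueModel-class].
#' @param gs a [StandardizedGenotypes-class], or a numeric matrix of
#'   standardized genotype rows.
#' @return numeric vector of per-patient indices.
#' @export
truePredictiveIndex <- function(model, gs) {
  stopifnot(is(model, "TrueModel"))
  X <- if (is(gs, "StandardizedGenotypes")) gs@values else as.matrix(gs)
  if (ncol(X) != model@p) stop("genotype width does not match model p")
  r <- rep(2 * model@mu, nrow(X))
  if (length(model@iGamma))
    r <- r + 2 * drop(X[, model@iGamma, drop = FALSE] %*% model@gamma)
  r
}
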