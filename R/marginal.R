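#' Single-marker association tests over the trial design
#'
#' For every column c of the design (prognostic and predictive candidates
#' alike), fits the least-squares model \code{Y ~ intercept + T + c} and
#' returns the two-sided t-test p-value for the column coefficient. The
#' treatment main effect is kept in the model so that interaction-column
#' tests are not confounded by an overall treatment effect; set
#' \code{adjustTreatment = FALSE} for the plain simple-regression variant
#' \code{Y ~ intercept + c}.
#'
#' @param design a [TrialDesign-class].
#' @param y numeric outcome vector.
#' @param adjustTreatment keep T in every per-column model (default TRUE).
#' @return numeric vector of 2p p-values, one per design column.
#' @export
marginalTests <- function(design, y, adjustTreatment = TRUE) {
  stopifnot(is(design, "TrialDesign"))
  X <- design@values
  n <- nrow(X)
  Z <- if (adjustTreatment) cbind(1, design@treatment) else cbind(rep(1, n))
  df <- n - ncol(Z) - 1L
  qz <- qr(Z)
  yr <- qr.resid(qz, y)
  Xr <- qr.resid(qz, X)
  nrm2 <- colSums(Xr^2)
  ok <- nrm2 > 1e-12
  if (!all(ok))
    warning(sum(!ok), " column(s) collinear with the adjustment terms; ",
            "their p-values are set to 1")
  b <- numeric(ncol(X))
  b[ok] <- colSums(Xr[, ok, drop = FALSE] * yr) / nrm2[ok]
  rss <- sum(yr^2) - b^2 * nrm2
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df) / sqrt(pmax(nrm2, 1e-300))
  tstat <- ifelse(ok & se > 0, b / se, 0)
  pv <- 2 * stats::pt(-abs(tstat), df)
  pv[!ok] <- 1
  pv
}

#' Bonferroni selection from a p-value vector
#'
#' Selects all indices with \eqn{p_j \le \alpha / m_{eff}}. By default
#' \code{mEff} is the number of tests; for correlated markers it can be
#' replaced by the effective number of tests from
#' [effectiveNumberOfMarkers()].
#'
#' @param pvalues numeric p-values.
#' @param alpha family-wise level in (0, 1).
#' @param mEff effective number of tests (default \code{length(pvalues)}).
#' @return integer vector of selected indices.
#' @export
bonferroniSelect <- function(pvalues, alpha = 0.05, mEff = length(pvalues)) {
  stopifnot(alpha > 0, alpha < 1, mEff > 0)
  which(pvalues <= alpha / mEff)
}

#' Benjamini-Hochberg step-up selection
#'
#' Sorted p-values are compared against the staircase \eqn{i\,q/m_{eff}};
#' all indices with rank at most the largest passing i are selected.
#'
#' @param pvalues numeric p-values.
#' @param q FDR level in (0, 1).
#' @param mEff effective number of tests (default \code{length(pvalues)});
#'   substituting a smaller effective count relaxes the staircase.
#' @return integer vector of selected indices.
#' @export
bhSelect <- function(pvalues, q = 0.05, mEff = length(pvalues)) {
  stopifnot(q > 0, q < 1, mEff > 0)
  m <- length(pvalues)
  o <- order(pvalues)
  passed <- which(pvalues[o] <= seq_len(m) * q / mEff)
  if (!length(passed)) return(integer(0))
  sort(o[seq_len(max(passed))])
}

#' Effective number of independent markers for a correlated panel
#'
#' Simulates the null distribution of the maximal single-marker |t|
#' statistic over all design columns (outcomes drawn i.i.d. standard
#' normal), takes its empirical (1 - alpha) quantile c, and returns the
#' number of independent tests that would share this critical value:
#' \deqn{p_{eff} = \log(1-\alpha) \,/\, \log(2\Phi(c) - 1),}
#' using the Gaussian approximation to the t null. Substituting
#' \eqn{p_{eff}} for the raw test count softens Bonferroni/BH corrections
#' and the mBIC2 penalty when markers are correlated.
#'
#' @param design a [TrialDesign-class].
#' @param alpha significance level of the max statistic (default 0.05).
#' @param B number of null replicates (default 1000; at least 200).
#' @param seed integer seed.
#' @return list with elements \code{pEff}, \code{criticalValue},
#'   \code{B}, \code{alpha}.
#' @export
effectiveNumberOfMarkers <- function(design, alpha = 0.05, B = 1000,
                                     seed = NULL) {
  stopifnot(is(design, "TrialDesign"), B >= 200)
  if (!is.null(seed)) set.seed(seed)
  X <- design@values
  n <- nrow(X)
  Z <- cbind(1, design@treatment)
  df <- n - 3L
  qz <- qr(Z)
  Xr <- qr.resid(qz, X)
  nrm <- sqrt(colSums(Xr^2))
  if (any(nrm < 1e-10)) stop("degenerate design: column collinear with T")
  Xu <- sweep(Xr, 2L, nrm, "/")
  maxT <- numeric(B)
  bs <- 200L # simulate outcomes in blocks to bound memory
  done <- 0L
  while (done < B) {
    nb <- min(bs, B - done)
    Yb <- matrix(stats::rnorm(n * nb), n, nb)
    Yb <- qr.resid(qz, Yb)
    Yb <- sweep(Yb, 2L, sqrt(colSums(Yb^2)), "/")
    r <- crossprod(Xu, Yb)            # correlations, m x nb
    tb <- abs(r) * sqrt(df / pmax(1 - r^2, 1e-12))
    maxT[done + seq_len(nb)] <- apply(tb, 2L, max)
    done <- done + nb
  }
  cv <- unname(stats::quantile(maxT, 1 - alpha))
  # invert through the same t null the statistics were drawn from; the
  # normal CDF would understate the tail at moderate n and inflate p_eff
  pEff <- log(1 - alpha) / log(2 * stats::pt(cv, df) - 1)
  list(pEff = pEff, criticalValue = cv, B = B, alpha = alpha)
}
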