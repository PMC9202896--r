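#' The mBIC2 model-selection criterion
#'
#' For a regression model containing k biomarker columns with residual sum
#' of squares RSS, evaluated against a pool of \code{mCandidates}
#' candidate regressors:
#' \deqn{mBIC2 = n\log RSS + k\log n + 2k\log(m/4) - 2\log(k!)}
#' (natural logs, m = \code{mCandidates}). The always-included treatment
#' effect is not counted in k. The sparsity penalty is calibrated so that
#' minimizing the criterion controls the FDR of selected regressors near
#' 0.05 when n and m are large and predictors are independent or weakly
#' correlated; for correlated panels \code{mCandidates} may be replaced by
#' the effective number of tests.
#'
#' @param n sample size.
#' @param rss residual sum of squares (> 0).
#' @param k number of biomarker columns in the model.
#' @param mCandidates number of candidate regressors (>= 4).
#' @return the criterion value (smaller is better).
#' @examples
#' mbic2Value(1000, 1, 1, 200)  # log(1000) + 2*log(50)
#' @export
mbic2Value <- function(n, rss, k, mCandidates) {
  if (rss <= 0) stop("rss must be positive")
  if (mCandidates < 4) stop("mCandidates must be at least 4")
  if (k < 0 || k > mCandidates) stop("k must lie in 0..mCandidates")
  n * log(rss) + k * log(n) + 2 * k * log(mCandidates / 4) - 2 * lfactorial(k)
}

# Penalty increment when growing a model from k to k+1 columns.
.mbic2Step <- function(n, k, mCandidates) {
  log(n) + 2 * log(mCandidates / 4) - 2 * log(k + 1)
}

#' Stepwise minimization of mBIC2 over the trial design
#'
#' Screens the design columns by absolute correlation with the outcome
#' (after residualizing the outcome on intercept and treatment), keeps the
#' top \code{screenSize}, then alternates greedy forward additions and
#' backward deletions of the mBIC2 criterion until no single move improves
#' it. The intercept and the treatment effect are always in the fitted
#' regression but never penalized. The returned coefficients are the
#' plain least-squares refit on the final support.
#'
#' @param design a [TrialDesign-class].
#' @param y numeric outcome vector.
#' @param mCandidates candidate count used in the penalty; defaults to the
#'   number of design columns (2p). Substitute the effective number of
#'   tests for correlated panels.
#' @param screenSize number of columns kept after screening; default
#'   \code{min(candidates, n/2)}.
#' @param candidateRoles which design-column roles may enter the model;
#'   restricting to \code{"prognostic"} gives the main-effects-only
#'   selection used by efficacy Method 2a.
#' @return a [SelectionResult-class] with method tag \code{"mbic2"}.
#' @export
mbic2Search <- function(design, y, mCandidates = NULL, screenSize = NULL,
                        candidateRoles = c("prognostic", "predictive")) {
  stopifnot(is(design, "TrialDesign"))
  candidateRoles <- match.arg(candidateRoles, several.ok = TRUE)
  X <- design@values
  n <- nrow(X)
  if (n <= 10) stop("need n > 10")
  pool <- which(design@roles %in% candidateRoles)
  if (is.null(mCandidates)) mCandidates <- length(pool)
  if (is.null(screenSize)) screenSize <- min(length(pool), floor(n / 2))

  # Frisch-Waugh: with intercept and T always in the model, subset RSS
  # equals the RSS of the T-residualized outcome on T-residualized columns.
  qz <- qr(cbind(1, design@treatment))
  yr <- qr.resid(qz, y)
  Xr <- qr.resid(qz, X[, pool, drop = FALSE])

  cand <- pool
  if (screenSize < length(pool)) {
    sc <- abs(crossprod(Xr, yr)) / sqrt(colSums(Xr^2))
    keep <- sort(order(-sc)[seq_len(screenSize)])
    cand <- pool[keep]
    Xr <- Xr[, keep, drop = FALSE]
  }
  sel <- .stepwiseCore(Xr, yr, n, mCandidates)
  .finalizeSelection(design, y, cand[sel], "mbic2")
}

# Greedy forward/backward minimization of mBIC2 on residualized data.
# Returns the (local-path) indices of the selected columns of Xr.
.stepwiseCore <- function(Xr, yr, n, mCandidates) {
  m <- ncol(Xr)
  rssOf <- function(idx) {
    if (!length(idx)) return(sum(yr^2))
    f <- .lm.fit(Xr[, idx, drop = FALSE], yr)
    sum(f$residuals^2)
  }
  sel <- integer(0)
  # Incremental orthogonalization for the forward scan: Q holds an
  # orthonormal basis of the selected columns, Xw/yw the residuals of the
  # candidates/outcome against it.
  Xw <- Xr
  yw <- yr
  crit <- mbic2Value(n, sum(yr^2), 0L, mCandidates)
  repeat {
    improved <- FALSE
    # forward: repeatedly add the best column while the criterion drops
    repeat {
      avail <- setdiff(seq_len(m), sel)
      if (!length(avail)) break
      nrm2 <- colSums(Xw[, avail, drop = FALSE]^2)
      ok <- nrm2 > 1e-10
      if (!any(ok)) break
      gain <- numeric(length(avail))
      gain[ok] <- (colSums(Xw[, avail[ok], drop = FALSE] * yw))^2 / nrm2[ok]
      rssCur <- sum(yw^2)
      best <- which.max(gain * ok) # ties: which.max takes the lowest index
      newRss <- rssCur - gain[best]
      if (newRss <= 1e-12) break
      newCrit <- mbic2Value(n, newRss, length(sel) + 1L, mCandidates)
      if (newCrit >= crit - 1e-10) break
      j <- avail[best]
      qj <- Xw[, j] / sqrt(nrm2[best])
      Xw <- Xw - tcrossprod(qj, crossprod(Xw, qj))
      yw <- yw - qj * sum(qj * yr)
      sel <- c(sel, j)
      crit <- newCrit
      improved <- TRUE
    }
    # backward: repeatedly drop the member whose removal helps most
    repeat {
      if (!length(sel)) break
      drops <- vapply(seq_along(sel), function(i) {
        mbic2Value(n, rssOf(sel[-i]), length(sel) - 1L, mCandidates)
      }, numeric(1))
      i <- which.min(drops)
      if (drops[i] >= crit - 1e-10) break
      sel <- sel[-i]
      crit <- drops[i]
      improved <- TRUE
      # rebuild the working residuals for any further forward pass
      if (length(sel)) {
        qs <- qr(Xr[, sel, drop = FALSE])
        Xw <- qr.resid(qs, Xr)
        yw <- qr.resid(qs, yr)
      } else {
        Xw <- Xr; yw <- yr
      }
    }
    if (!improved) break
    # refresh working residuals before the next forward pass
    if (length(sel)) {
      qs <- qr(Xr[, sel, drop = FALSE])
      Xw <- qr.resid(qs, Xr)
      yw <- qr.resid(qs, yr)
    } else {
      Xw <- Xr; yw <- yr
    }
  }
  sort(sel)
}

#' Exhaustive best-subset minimization of mBIC2 (small-problem oracle)
#'
#' Evaluates the criterion over all \eqn{2^{2p}} subsets of design
#' columns and returns the global minimizer. Intended as an independent
#' check of [mbic2Search()] on small problems; refuses designs wider than
#' 15 columns.
#'
#' @inheritParams mbic2Search
#' @return a [SelectionResult-class] with method tag \code{"mbic2-exhaustive"}.
#' @export
mbic2Exhaustive <- function(design, y, mCandidates = NULL) {
  stopifnot(is(design, "TrialDesign"))
  X <- design@values
  m <- ncol(X)
  if (m > 15) stop("exhaustive search refuses more than 15 columns")
  n <- nrow(X)
  if (is.null(mCandidates)) mCandidates <- m
  qz <- qr(cbind(1, design@treatment))
  yr <- qr.resid(qz, y)
  Xr <- qr.resid(qz, X)
  bestCrit <- Inf
  bestSet <- integer(0)
  for (code in 0:(2^m - 1)) {
    idx <- which(bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) != 0L)
    rss <- if (length(idx)) {
      sum(.lm.fit(Xr[, idx, drop = FALSE], yr)$residuals^2)
    } else sum(yr^2)
    if (rss <= 1e-12) next
    cr <- mbic2Value(n, rss, length(idx), mCandidates)
    if (cr < bestCrit - 1e-12) {
      bestCrit <- cr
      bestSet <- idx
    }
  }
  .finalizeSelection(design, y, bestSet, "mbic2-exhaustive")
}
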