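#' Benjamini-Hochberg lambda sequence for SLOPE
#'
#' \deqn{\lambda_j = \sigma\,\Phi^{-1}(1 - j\,q/(2m)),\quad j = 1..m,}
#' floored at zero: the sequence of decaying BH thresholds that gives
#' SLOPE its FDR-control calibration for (near-)orthogonal designs with
#' unit-L2-norm columns.
#'
#' @param m number of candidate regressors.
#' @param q FDR parameter in (0, 1).
#' @param sigma noise scale (> 0).
#' @return numeric nonincreasing vector of length m.
#' @examples
#' bhLambda(200, 0.05)[1]  # qnorm(1 - 0.05/400)
#' @export
bhLambda <- function(m, q = 0.05, sigma = 1) {
  stopifnot(q > 0, q < 1, sigma > 0, m >= 1)
  pmax(sigma * stats::qnorm(1 - seq_len(m) * q / (2 * m)), 0)
}

#' Proximal operator of the sorted-L1 (OWL) norm
#'
#' Returns \eqn{\mathrm{argmin}_b\; \tfrac12\|b - v\|^2 +
#' \sum_j \lambda_j |b|_{(j)}} for a nonincreasing nonnegative
#' \eqn{\lambda}. Computed exactly by the sign/permutation reduction:
#' sort |v| in decreasing order, subtract \eqn{\lambda}, project onto the
#' nonincreasing cone by isotonic regression (PAVA), clip at zero, undo
#' the permutation and restore signs.
#'
#' @param v numeric vector.
#' @param lambda numeric nonincreasing nonnegative vector,
#'   \code{length(v)}.
#' @return numeric vector, the proximal point.
#' @export
proxSortedL1 <- function(v, lambda) {
  if (length(lambda) != length(v))
    stop("lambda must have the same length as v")
  if (is.unsorted(rev(lambda)) || any(lambda < 0))
    stop("lambda must be nonincreasing and nonnegative")
  av <- abs(v)
  o <- order(av, decreasing = TRUE)
  u <- av[o] - lambda
  # nonincreasing isotonic LS fit = -(nondecreasing fit of -u)
  h <- if (length(u) > 1) -stats::isoreg(-u)$yf else u
  b <- pmax(h, 0)
  out <- numeric(length(v))
  out[o] <- b
  out * sign(v)
}

#' Solve the SLOPE program by accelerated proximal gradient
#'
#' Minimizes \eqn{\|Y - Xb\|_2^2 + \sum_j \lambda_j |b|_{(j)}} (FISTA with
#' objective-restart). Columns of X are expected on the unit-L2-norm
#' scale for the BH lambda calibration to apply.
#'
#' @param X numeric n x m design.
#' @param y numeric outcome.
#' @param lambda nonincreasing nonnegative vector of length m.
#' @param tol relative objective-change tolerance (default 1e-8).
#' @param maxIter iteration cap (default 5000).
#' @param b0 optional warm start.
#' @return list with \code{b} (coefficients), \code{objective},
#'   \code{iterations}, \code{converged}.
#' @export
solveSlope <- function(X, y, lambda, tol = 1e-8, maxIter = 5000, b0 = NULL) {
  m <- ncol(X)
  stopifnot(length(lambda) == m)
  obj <- function(b, r) sum(r^2) + sum(sort(abs(b), decreasing = TRUE) * lambda)
  # Lipschitz constant of the gradient of ||y - Xb||^2 is 2*||X||_2^2
  L <- 2 * .specNorm2(X)
  step <- 1 / L
  b <- if (is.null(b0)) numeric(m) else b0
  z <- b
  tPar <- 1
  r <- y - drop(X %*% b)
  fPrev <- obj(b, r)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    rz <- y - drop(X %*% z)
    g <- -2 * drop(crossprod(X, rz))
    bNew <- proxSortedL1(z - step * g, step * lambda)
    rNew <- y - drop(X %*% bNew)
    fNew <- obj(bNew, rNew)
    if (fNew > fPrev) {            # restart acceleration at the last iterate
      tPar <- 1
      z <- b
      rz <- y - drop(X %*% z)
      g <- -2 * drop(crossprod(X, rz))
      bNew <- proxSortedL1(z - step * g, step * lambda)
      rNew <- y - drop(X %*% bNew)
      fNew <- obj(bNew, rNew)
    }
    tNew <- (1 + sqrt(1 + 4 * tPar^2)) / 2
    z <- bNew + ((tPar - 1) / tNew) * (bNew - b)
    b <- bNew
    tPar <- tNew
    if (abs(fPrev - fNew) <= tol * max(1, abs(fPrev))) {
      fPrev <- fNew
      converged <- TRUE
      break
    }
    fPrev <- fNew
  }
  if (!converged)
    warning("SLOPE solver reached maxIter without meeting tol")
  list(b = b, objective = fPrev, iterations = it, converged = converged)
}

# Squared spectral norm via a few power iterations (deterministic start).
.specNorm2 <- function(X) {
  v <- rep(1 / sqrt(ncol(X)), ncol(X))
  s <- 0
  for (i in 1:30) {
    w <- drop(crossprod(X, X %*% v))
    sNew <- sqrt(sum(w^2))
    if (sNew == 0) return(1e-12)
    v <- w / sNew
    if (abs(sNew - s) < 1e-8 * sNew) break
    s <- sNew
  }
  sNew
}

#' SLOBE: iteratively reweighted empirical-Bayes SLOPE selection
#'
#' Runs weighted SLOPE where each coordinate's penalty is scaled by one
#' minus the posterior probability that the coordinate is a true
#' predictor, iterating weight and noise-scale updates to convergence of
#' the support. The posterior is computed under a two-group normal model
#' on the gradient-adjusted coordinate statistics
#' \eqn{z_j = b_j + X_j^\top(y - Xb)} (approximately
#' \eqn{N(b_j^{true}, \sigma^2)} for unit-norm columns): null
#' \eqn{N(0, \sigma^2)} versus signal \eqn{N(0, \sigma^2 + \tau^2)}, with
#' the sparsity fraction \eqn{\theta}, signal variance \eqn{\tau^2} and
#' \eqn{\sigma} re-estimated each pass. Strongly supported coordinates
#' therefore receive a shrunken penalty (debiasing) while null-like ones
#' keep the full SLOPE penalty, which preserves FDR control.
#'
#' For wide designs (\code{2p >= screenThreshold}) an initial screen
#' keeps the \code{screenSize} columns most correlated with the outcome
#' and the FDR parameter is tightened to
#' \code{q * screenSize / (2p)} to account for the discarded columns.
#'
#' @param design a [TrialDesign-class].
#' @param y numeric outcome.
#' @param q nominal FDR level (default 0.05).
#' @param screenThreshold design width from which screening kicks in
#'   (default 1000 columns).
#' @param screenSize number of columns kept by the screen (default 500).
#' @param tol,maxIter inner SLOPE solver controls.
#' @param maxOuter cap on reweighting passes (default 20).
#' @param sigma known noise SD; \code{NULL} (default) estimates it,
#'   initialized from cross-validated lasso residuals.
#' @param seed integer seed (cross-validation folds).
#' @return a [SelectionResult-class] with method tag \code{"slobe"};
#'   coefficients are the least-squares refit on the selected support.
#' @export
slobe <- function(design, y, q = 0.05, screenThreshold = 1000,
                  screenSize = 500, tol = 1e-7, maxIter = 1000,
                  maxOuter = 20, sigma = NULL, seed = NULL) {
  stopifnot(is(design, "TrialDesign"), q > 0, q < 1)
  if (!is.null(seed)) set.seed(seed)
  X <- design@values
  m <- ncol(X)
  n <- nrow(X)
  # treatment and intercept are unpenalized: remove them from the outcome
  qz <- qr(cbind(1, design@treatment))
  yr <- qr.resid(qz, y)

  cand <- seq_len(m)
  qEff <- q
  if (m >= screenThreshold && screenSize < m) {
    sc <- abs(drop(crossprod(X, yr)))
    cand <- sort(order(-sc)[seq_len(screenSize)])
    qEff <- q * screenSize / m
  }
  Xs <- X[, cand, drop = FALSE]
  ms <- length(cand)

  sigmaKnown <- !is.null(sigma)
  if (!sigmaKnown) {
    # cross-validated lasso prediction error: an overfit-robust estimate
    # of the noise variance even when the screen keeps more columns than
    # samples (training residuals would collapse there)
    cvfit <- glmnet::cv.glmnet(Xs, yr, nfolds = 5, standardize = FALSE)
    sigma <- sqrt(min(cvfit$cvm))
  }
  lamBase <- bhLambda(ms, qEff, 1)

  w <- rep(1, ms)
  b <- numeric(ms)
  suppPrev <- integer(0)
  for (outer in seq_len(maxOuter)) {
    # the solver's objective carries ||y - Xb||^2 without the 1/2 factor,
    # so the BH sequence enters doubled to give the standard SLOPE
    # thresholds (prox at lambda/2 under orthogonality)
    lam <- sort(2 * sigma * w * lamBase, decreasing = TRUE)
    fit <- suppressWarnings(
      solveSlope(Xs, yr, lam, tol = tol, maxIter = maxIter, b0 = b))
    b <- fit$b
    supp <- which(b != 0)
    # empirical-Bayes update on gradient-adjusted statistics
    z <- b + drop(crossprod(Xs, yr - drop(Xs %*% b)))
    theta <- (length(supp) + 1) / (ms + 2)
    tau2 <- max(mean(z[supp]^2) - sigma^2, sigma^2 / 2)
    if (!length(supp)) tau2 <- sigma^2
    d1 <- stats::dnorm(z, 0, sqrt(sigma^2 + tau2))
    d0 <- stats::dnorm(z, 0, sigma)
    pi1 <- theta * d1 / (theta * d1 + (1 - theta) * d0)
    w <- pmax(1 - pi1, 1e-3)
    if (!sigmaKnown && length(supp) < n / 2) {
      rss <- sum((yr - drop(Xs %*% b))^2)
      sigma <- sqrt(rss / (n - length(supp) - 2))
    }
    if (outer > 1 && identical(supp, suppPrev)) break
    suppPrev <- supp
  }
  .finalizeSelection(design, y, cand[b != 0], "slobe")
}
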