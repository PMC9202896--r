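#' Two-stage cross-validated adaptive lasso
#'
#' Stage 1 fits an ordinary lasso over the 2p design columns with the
#' penalty level chosen by k-fold cross-validation (minimum-CV rule).
#' Stage 2 refits a weighted lasso on the stage-1 support with weights
#' \eqn{\hat\omega_j = 1/|\hat b_{j,lasso}|}; columns zeroed in stage 1
#' are excluded. The treatment effect is unpenalized throughout. The
#' returned coefficients are the least-squares refit on the stage-2
#' support (the penalized stage-2 coefficients are kept in the
#' \code{penalized} attribute).
#'
#' @param design a [TrialDesign-class].
#' @param y numeric outcome.
#' @param folds cross-validation folds (default 10).
#' @param nLambda size of the lambda grid (default 100).
#' @param seed integer seed for fold assignment.
#' @return a [SelectionResult-class] with method tag \code{"adalasso"}.
#' @export
adaptiveLasso <- function(design, y, folds = 10, nLambda = 100, seed = NULL) {
  stopifnot(is(design, "TrialDesign"))
  n <- nrow(design@values)
  if (n < 2 * folds) stop("need n >= 2 * folds")
  if (!is.null(seed)) set.seed(seed)
  X <- design@values
  m <- ncol(X)
  # treatment rides along unpenalized as an extra first column
  Xa <- cbind(design@treatment, X)
  pf1 <- c(0, rep(1, m))
  foldid <- sample(rep_len(seq_len(folds), n))
  cv1 <- glmnet::cv.glmnet(Xa, y, foldid = foldid, penalty.factor = pf1,
                           nlambda = nLambda, standardize = FALSE)
  b1 <- drop(stats::coef(cv1, s = "lambda.min"))[-(1:2)] # drop int., T
  supp1 <- which(b1 != 0)
  if (!length(supp1)) {
    out <- .finalizeSelection(design, y, integer(0), "adalasso")
    attr(out, "penalized") <- numeric(0)
    return(out)
  }
  w <- 1 / abs(b1[supp1])
  if (length(supp1) == 1L) {
    # glmnet needs >= 2 penalized columns; a single survivor is kept as-is
    supp2 <- supp1
    b2 <- b1[supp1]
  } else {
    Xa2 <- cbind(design@treatment, X[, supp1, drop = FALSE])
    cv2 <- glmnet::cv.glmnet(Xa2, y, foldid = foldid,
                             penalty.factor = c(0, w),
                             nlambda = nLambda, standardize = FALSE)
    b2 <- drop(stats::coef(cv2, s = "lambda.min"))[-(1:2)]
    supp2 <- supp1[b2 != 0]
    b2 <- b2[b2 != 0]
  }
  out <- .finalizeSelection(design, y, supp2, "adalasso")
  attr(out, "penalized") <- stats::setNames(b2, colnames(X)[supp2])
  out
}
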