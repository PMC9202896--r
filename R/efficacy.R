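#' Treatment-efficacy testing strategies
#'
#' Five strategies to test, at level \code{alpha}, whether a treatment is
#' efficacious in the whole trial population or in a biomarker-defined
#' subgroup:
#' \describe{
#'   \item{Method 1 ([efficacyMethod1()])}{two-sample t-test between arms,
#'     ignoring biomarkers.}
#'   \item{Method 2 ([efficacyMethod2()])}{t-test of the treatment
#'     coefficient in the reduced regression model whose prognostic and
#'     predictive markers are chosen by a selector (mBIC2 by default) on
#'     the full sample.}
#'   \item{Method 2a ([efficacyMethod2a()])}{as Method 2 but the selector
#'     sees only prognostic columns; interactions are ignored, so the
#'     residual variance still carries the predictive contributions.}
#'   \item{Method 3 ([efficacyMethod3()])}{sample splitting: select and
#'     fit on a training half (arm-stratified), predict individual
#'     treatment effects on the held-out half, and t-test the arms inside
#'     the predicted responder subgroup. If no predictive marker is
#'     selected no subgroup exists and the method does not reject.}
#'   \item{Method 4 ([efficacyMethod4()])}{Bonferroni combination:
#'     reject if Method 2 rejects at alpha/2 or Method 3 rejects at
#'     alpha/2 (one fixed split per dataset).}
#' }
#' The mu-test of Methods 2/2a is the naive post-selection t-test of the
#' refitted model, matching common practice; its anti-conservativeness
#' under selection is a documented caveat.
#'
#' @name efficacy
NULL

.twoSampleT <- function(y, tr) {
  # pooled-variance two-sided two-sample t-test
  y1 <- y[tr > 0]; y0 <- y[tr < 0]
  n1 <- length(y1); n0 <- length(y0)
  if (n1 < 2 || n0 < 2) stop("each arm needs at least 2 samples")
  sp2 <- ((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) / (n1 + n0 - 2)
  tstat <- (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  2 * stats::pt(-abs(tstat), n1 + n0 - 2)
}

.muPValue <- function(design, y, sel) {
  # two-sided t-test of the treatment coefficient in the OLS refit
  X <- design@values
  p <- ncol(X) %/% 2L
  cols <- c(sel@iBeta, p + sel@iGamma)
  M <- cbind(1, design@treatment, X[, cols, drop = FALSE])
  qm <- qr(M)
  cf <- qr.coef(qm, y)
  if (is.na(cf[2])) return(1)
  res <- qr.resid(qm, y)
  df <- nrow(M) - qm$rank
  r <- qm$rank
  Rmat <- qr.R(qm)[seq_len(r), seq_len(r), drop = FALSE]
  Vpiv <- chol2inv(Rmat)
  piv <- qm$pivot[seq_len(r)]
  pos <- match(2L, piv)
  se <- sqrt(sum(res^2) / df * Vpiv[pos, pos])
  2 * stats::pt(-abs(cf[2] / se), df)
}

#' @rdname efficacy
#' @param y numeric outcome vector.
#' @param treatment numeric -1/+1 arm labels.
#' @param alpha significance level (default 0.05).
#' @return an [EfficacyOutcome-class].
#' @export
efficacyMethod1 <- function(y, treatment, alpha = 0.05) {
  pv <- .twoSampleT(y, treatment)
  new("EfficacyOutcome", method = "M1", reject = pv <= alpha,
      pValues = c(ttest = pv), subgroupSize = NA_integer_,
      subgroupDefined = NA)
}

#' @rdname efficacy
#' @param design a [TrialDesign-class].
#' @param selector function with signature
#'   \code{(design, y, candidateRoles) -> SelectionResult}; default
#'   [mbic2Search()]. Only Method 2a passes a restricted
#'   \code{candidateRoles}.
#' @export
efficacyMethod2 <- function(design, y, alpha = 0.05, selector = mbic2Search) {
  sel <- selector(design, y)
  pv <- unname(.muPValue(design, y, sel))
  new("EfficacyOutcome", method = "M2", reject = pv <= alpha,
      pValues = c(mu = pv), subgroupSize = NA_integer_,
      subgroupDefined = NA)
}

#' @rdname efficacy
#' @export
efficacyMethod2a <- function(design, y, alpha = 0.05, selector = mbic2Search) {
  sel <- selector(design, y, candidateRoles = "prognostic")
  pv <- unname(.muPValue(design, y, sel))
  new("EfficacyOutcome", method = "M2a", reject = pv <= alpha,
      pValues = c(mu = pv), subgroupSize = NA_integer_,
      subgroupDefined = NA)
}

#' @rdname efficacy
#' @export
efficacyMethod3 <- function(design, y, alpha = 0.05, splitFraction = 0.5,
                            selector = mbic2Search, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- .armStratifiedSplit(design@treatment, splitFraction)
  .method3Core(design, y, alpha, train = sp$train, test = sp$test, selector)
}

#' @rdname efficacy
#' @param splitFraction fraction of patients in the training half
#'   (default 0.5), stratified by arm.
#' @param seed integer seed for the split.
#' @export
efficacyMethod4 <- function(design, y, alpha = 0.05, splitFraction = 0.5,
                            selector = mbic2Search, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m2 <- efficacyMethod2(design, y, alpha / 2, selector)
  sp <- .armStratifiedSplit(design@treatment, splitFraction)
  m3 <- .method3Core(design, y, alpha / 2, sp$train, sp$test, selector)
  new("EfficacyOutcome", method = "M4",
      reject = m2@reject || m3@reject,
      pValues = c(mu = unname(m2@pValues["mu"]),
                  subgroup = unname(m3@pValues["subgroup"])),
      subgroupSize = m3@subgroupSize,
      subgroupDefined = m3@subgroupDefined)
}

.armStratifiedSplit <- function(treatment, splitFraction = 0.5) {
  idx1 <- which(treatment > 0)
  idx0 <- which(treatment < 0)
  tr <- c(sample(idx1, floor(length(idx1) * splitFraction)),
          sample(idx0, floor(length(idx0) * splitFraction)))
  list(train = sort(tr), test = setdiff(seq_along(treatment), tr))
}

.method3Core <- function(design, y, alpha, train, test, selector) {
  if (length(train) < 20) stop("training half too small")
  p <- ncol(design@values) %/% 2L
  Xprog <- design@values[, seq_len(p), drop = FALSE]
  # re-standardize the genotype block within the training half so the
  # selector's effect-size calibration holds there
  vTrain <- Xprog[train, , drop = FALSE]
  ctr <- colMeans(vTrain)
  vTrain <- sweep(vTrain, 2L, ctr, "-")
  nrm <- sqrt(colSums(vTrain^2))
  nrm[nrm < 1e-12] <- 1
  vTrain <- sweep(vTrain, 2L, nrm, "/")
  trArm <- design@treatment[train]
  trDesign <- new("TrialDesign",
                  values = cbind(vTrain, vTrain * trArm),
                  roles = rep(c("prognostic", "predictive"), each = p),
                  treatment = trArm, snpIds = design@snpIds)
  sel <- selector(trDesign, y[train])
  noSubgroup <- function(defined) {
    new("EfficacyOutcome", method = "M3", reject = FALSE,
        pValues = c(subgroup = NA_real_), subgroupSize = 0L,
        subgroupDefined = defined)
  }
  if (!length(sel@iGamma)) return(noSubgroup(FALSE))
  # test rows on the training scale: same centering and norm as training
  vTest <- sweep(Xprog[test, , drop = FALSE], 2L, ctr, "-")
  vTest <- sweep(vTest, 2L, nrm, "/")
  rhat <- predictedIndex(sel, vTest)
  sub <- test[rhat > 0]
  trt <- design@treatment[sub]
  if (sum(trt > 0) < 2 || sum(trt < 0) < 2) {
    warning("responder subgroup lacks two patients per arm")
    return(noSubgroup(TRUE))
  }
  pv <- .twoSampleT(y[sub], trt)
  new("EfficacyOutcome", method = "M3", reject = pv <= alpha,
      pValues = c(subgroup = pv), subgroupSize = length(sub),
      subgroupDefined = TRUE)
}
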