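#' Least-squares fit of a reduced prognostic/predictive model
#'
#' Ordinary least squares of the outcome on intercept, treatment, the
#' selected prognostic genotype columns and the selected predictive
#' (genotype x treatment) columns:
#' \deqn{Y_i = c + \mu T_i + \sum_{j \in \hat I_\beta} \beta_j X_{ij}
#'   + \sum_{j \in \hat I_\gamma} \gamma_j X_{ij} T_i + \epsilon_i.}
#' Rank-deficient supports are repaired by dropping later-indexed
#' collinear columns with a warning.
#'
#' @param design a [TrialDesign-class].
#' @param y numeric outcome vector.
#' @param iBeta,iGamma integer SNP index sets (values in 1..p).
#' @param method tag stored in the result.
#' @return a [SelectionResult-class].
#' @export
fitSelectedModel <- function(design, y, iBeta, iGamma, method = "custom") {
  stopifnot(is(design, "TrialDesign"))
  p <- ncol(design@values) %/% 2L
  iBeta <- sort(unique(as.integer(iBeta)))
  iGamma <- sort(unique(as.integer(iGamma)))
  if (any(c(iBeta, iGamma) < 1L) || any(c(iBeta, iGamma) > p))
    stop("selected indices must lie in 1..p")
  .finalizeSelection(design, y, c(iBeta, p + iGamma), method)
}

# Shared refit: maps design-column indices to SNP index sets, runs OLS on
# [1, T, selected columns] and packs a SelectionResult.
.finalizeSelection <- function(design, y, cols, method) {
  X <- design@values
  p <- ncol(X) %/% 2L
  cols <- sort(unique(as.integer(cols)))
  M <- cbind(`(Intercept)` = 1, T = design@treatment,
             X[, cols, drop = FALSE])
  qm <- qr(M)
  if (qm$rank < ncol(M)) {
    keep <- qm$pivot[seq_len(qm$rank)]
    droppedCols <- setdiff(seq_len(ncol(M)), keep)
    dropped <- droppedCols[droppedCols > 2L] - 2L
    if (length(dropped)) {
      warning("dropping ", length(dropped), " collinear selected column(s)")
      cols <- cols[-dropped]
      M <- cbind(1, design@treatment, X[, cols, drop = FALSE])
      qm <- qr(M)
    }
  }
  cf <- qr.coef(qm, y)
  cf[is.na(cf)] <- 0
  isProg <- cols <= p
  new("SelectionResult",
      iBeta = cols[isProg],
      iGamma = cols[!isProg] - p,
      beta = unname(cf[-(1:2)][isProg]),
      gamma = unname(cf[-(1:2)][!isProg]),
      muHat = unname(cf[2]),
      intercept = unname(cf[1]),
      method = method)
}

#' Predicted individual treatment effect from a fitted model
#'
#' \deqn{\hat R(x) = 2\big(\hat\mu + \sum_{j \in \hat I_\gamma}
#'   \hat\gamma_j x_j\big)} evaluated per patient; patients with
#' \eqn{\hat R > 0} are predicted responders.
#'
#' @param sel a [SelectionResult-class].
#' @param gs a [StandardizedGenotypes-class] or numeric matrix on the
#'   standardized scale used at fitting time.
#' @return numeric vector of predicted indices.
#' @export
predictedIndex <- function(sel, gs) {
  stopifnot(is(sel, "SelectionResult"))
  X <- if (is(gs, "StandardizedGenotypes")) gs@values else as.matrix(gs)
  r <- rep(2 * sel@muHat, nrow(X))
  if (length(sel@iGamma))
    r <- r + 2 * drop(X[, sel@iGamma, drop = FALSE] %*% sel@gamma)
  r
}

#' Standardized mean squared error of the predictive index
#'
#' \deqn{MSE = \sum_i (R_i - \hat R_i)^2 / \sum_i R_i^2.} Equal to 0 for a
#' perfect fit and 1 for the trivial estimate \eqn{\hat R \equiv 0};
#' invariant to rescaling both arguments by the same nonzero constant.
#'
#' @param rTrue,rHat numeric vectors of true and estimated indices.
#' @return nonnegative scalar.
#' @export
mseIndex <- function(rTrue, rHat) {
  stopifnot(length(rTrue) == length(rHat))
  denom <- sum(rTrue^2)
  if (denom <= 0) stop("true predictive index is identically zero")
  sum((rTrue - rHat)^2) / denom
}

#' Responder classification rates
#'
#' Positive detection rate: percentage of true responders (R > 0)
#' predicted responsive (\eqn{\hat R > 0}). Negative detection rate:
#' percentage of true non-responders (R < 0) wrongly predicted
#' responsive. Also reported: the share of predicted responders whose
#' true index is negative (\code{ndrAmongPredicted}), the same errors
#' normalized by the predicted-responder count. Ties \eqn{\hat R = 0} (or
#' R = 0) count as non-responders. Empty denominators yield \code{NaN},
#' which callers should drop from averages.
#'
#' @param rTrue,rHat numeric vectors of true and estimated indices.
#' @return named numeric vector \code{c(pdr, ndr, ndrAmongPredicted)}
#'   in percent.
#' @export
responderRates <- function(rTrue, rHat) {
  stopifnot(length(rTrue) == length(rHat))
  predPos <- rHat > 0
  pdr <- 100 * sum(rTrue > 0 & predPos) / sum(rTrue > 0)
  ndr <- 100 * sum(rTrue < 0 & predPos) / sum(rTrue < 0)
  ndrAmong <- 100 * sum(rTrue < 0 & predPos) / sum(predPos)
  c(pdr = pdr, ndr = ndr, ndrAmongPredicted = ndrAmong)
}

#' Power and FDR of a biomarker selection against the generative truth
#'
#' Under the strict definition a selected marker is a true positive iff
#' its SNP index appears in the truth with the same role (prognostic and
#' predictive matched separately). Under the cluster-relaxed definition a
#' selection is a true positive iff its LD cluster contains a true marker
#' of the same role. Power is reported per role (fraction of true markers
#' covered) and FDR pools both roles, with the 0/0 convention equal to 0.
#'
#' @param truth a [TrueModel-class].
#' @param sel a [SelectionResult-class].
#' @param clusters integer cluster labels of the p SNPs (required for
#'   \code{mode = "cluster"}).
#' @param mode \code{"strict"} or \code{"cluster"}.
#' @return named numeric vector with elements \code{powerPrognostic},
#'   \code{powerPredictive}, \code{power} (both roles pooled), \code{fdr},
#'   \code{nSelected}.
#' @export
selectionMetrics <- function(truth, sel, clusters = NULL,
                             mode = c("strict", "cluster")) {
  mode <- match.arg(mode)
  stopifnot(is(truth, "TrueModel"), is(sel, "SelectionResult"))
  if (mode == "cluster" && is.null(clusters))
    stop("cluster mode requires cluster labels")
  roleStats <- function(selIdx, trueIdx) {
    if (mode == "strict") {
      tp <- sum(selIdx %in% trueIdx)
      covered <- sum(trueIdx %in% selIdx)
    } else {
      tc <- clusters[trueIdx]
      tp <- sum(clusters[selIdx] %in% tc)
      covered <- sum(tc %in% clusters[selIdx])
    }
    c(tp = tp, fp = length(selIdx) - tp,
      covered = covered, nTrue = length(trueIdx))
  }
  sb <- roleStats(sel@iBeta, truth@iBeta)
  sg <- roleStats(sel@iGamma, truth@iGamma)
  nSel <- length(sel@iBeta) + length(sel@iGamma)
  fp <- sb[["fp"]] + sg[["fp"]]
  fdr <- if (nSel == 0) 0 else fp / nSel
  powOf <- function(s) if (s[["nTrue"]] == 0) NA_real_ else
    s[["covered"]] / s[["nTrue"]]
  nTrue <- sb[["nTrue"]] + sg[["nTrue"]]
  c(powerPrognostic = powOf(sb),
    powerPredictive = powOf(sg),
    power = if (nTrue == 0) NA_real_ else
      (sb[["covered"]] + sg[["covered"]]) / nTrue,
    fdr = fdr,
    nSelected = nSel)
}
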