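#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' SnpGenotypes: a panel of SNP dosages for a trial cohort
#'
#' Container for an \code{n x p} matrix of allele dosages in \{0, 1, 2\}
#' (rows = samples, columns = SNPs), together with the per-SNP minor allele
#' frequencies used to generate or describe them, optional cluster labels
#' from correlation clumping, and sample/SNP identifiers.
#'
#' @slot dosages integer matrix, n samples by p SNPs, values in \{0, 1, 2\}.
#' @slot mafs numeric vector of length p, minor allele frequencies in
#'   (0, 0.5].
#' @slot clusterId integer vector of length p assigning each SNP to an LD
#'   cluster, or \code{NULL} when no clustering has been run.
#' @slot sampleIds,snpIds character identifiers.
#'
#' @seealso [simulateGenotypes()], [simulateBlockGenotypes()],
#'   [standardizeGenotypes()], [clumpSnps()]
#' @export
setClass("SnpGenotypes",
  representation(
    dosages   = "matrix",
    mafs      = "numeric",
    clusterId = "integerOrNULL",
    sampleIds = "character",
    snpIds    = "character"
  )
)

setValidity("SnpGenotypes", function(object) {
  d <- object@dosages
  msg <- character()
  if (nrow(d) < 2L) msg <- c(msg, "need at least 2 samples")
  if (ncol(d) < 1L) msg <- c(msg, "need at least 1 SNP")
  if (!all(d %in% c(0L, 1L, 2L)))
    msg <- c(msg, "dosages must be 0, 1 or 2")
  if (length(object@mafs) != ncol(d))
    msg <- c(msg, "mafs length must equal the number of SNPs")
  if (any(object@mafs <= 0) || any(object@mafs > 0.5))
    msg <- c(msg, "mafs must lie in (0, 0.5]")
  if (!is.null(object@clusterId) && length(object@clusterId) != ncol(d))
    msg <- c(msg, "clusterId length must equal the number of SNPs")
  if (length(object@sampleIds) != nrow(d))
    msg <- c(msg, "sampleIds length must equal the number of samples")
  if (length(object@snpIds) != ncol(d))
    msg <- c(msg, "snpIds length must equal the number of SNPs")
  if (length(msg)) msg else TRUE
})

#' StandardizedGenotypes: centered, unit-norm genotype columns
#'
#' Each column of \code{values} has zero mean and unit L2 norm (not unit
#' n-1 variance): the scaling under which per-marker effect sizes of the
#' form \eqn{c\sqrt{2\log p}} give sample-size-free detection power.
#'
#' @slot values numeric n x p matrix, columns centered and L2-normalized.
#' @slot mafs,clusterId,snpIds,sampleIds carried over from the source
#'   [SnpGenotypes-class] object.
#' @export
setClass("StandardizedGenotypes",
  representation(
    values    = "matrix",
    mafs      = "numeric",
    clusterId = "integerOrNULL",
    sampleIds = "character",
    snpIds    = "character"
  )
)

setValidity("StandardizedGenotypes", function(object) {
  v <- object@values
  msg <- character()
  cm <- colMeans(v)
  cn <- colSums(v^2)
  if (any(abs(cm) > 1e-8)) msg <- c(msg, "columns must have zero mean")
  if (any(abs(cn - 1) > 1e-8)) msg <- c(msg, "columns must have unit L2 norm")
  if (length(object@snpIds) != ncol(v))
    msg <- c(msg, "snpIds length must equal the number of SNPs")
  if (length(msg)) msg else TRUE
})

#' TrialDesign: the 2p-column prognostic + predictive design matrix
#'
#' Columns 1..p are the standardized genotypes (prognostic candidates
#' \eqn{X_j}); columns p+1..2p are their elementwise products with the
#' treatment arm \eqn{X_j T} (predictive candidates). Because
#' \eqn{|T_i| = 1}, the interaction columns keep unit L2 norm.
#'
#' @slot values numeric n x 2p matrix.
#' @slot roles character of length 2p, \code{"prognostic"} or
#'   \code{"predictive"}.
#' @slot treatment numeric length-n vector of arm labels in \{-1, +1\}.
#' @slot snpIds character of length p.
#' @export
setClass("TrialDesign",
  representation(
    values    = "matrix",
    roles     = "character",
    treatment = "numeric",
    snpIds    = "character"
  )
)

setValidity("TrialDesign", function(object) {
  msg <- character()
  m <- ncol(object@values)
  if (m %% 2L != 0L) msg <- c(msg, "design must have an even column count")
  if (length(object@roles) != m) msg <- c(msg, "roles length mismatch")
  if (!all(object@roles %in% c("prognostic", "predictive")))
    msg <- c(msg, "roles must be 'prognostic' or 'predictive'")
  if (length(object@treatment) != nrow(object@values))
    msg <- c(msg, "treatment length must equal the sample count")
  if (!all(object@treatment %in% c(-1, 1)))
    msg <- c(msg, "treatment labels must be -1 or +1")
  if (length(object@snpIds) != m %/% 2L) msg <- c(msg, "snpIds length mismatch")
  if (length(msg)) msg else TRUE
})

#' TrueModel: the generative truth of a simulated trial
#'
#' Index sets and coefficients of the generating model
#' \deqn{Y_i = \mu T_i + \sum_j \beta_j X_{ij} + \sum_j \gamma_j X_{ij} T_i
#'   + \epsilon_i,\qquad \epsilon_i \sim N(0, \sigma^2),}
#' where \eqn{\beta} acts on prognostic SNPs (set \code{iBeta}) and
#' \eqn{\gamma} on predictive SNPs (set \code{iGamma}); the sets may
#' overlap. Nonzero coefficients generated by [makeTrueModel()] have
#' magnitude \eqn{c_{eff}\sqrt{2\log p}} with Rademacher signs.
#'
#' @slot p integer, total number of candidate SNPs.
#' @slot iBeta,iGamma integer index sets of prognostic / predictive SNPs.
#' @slot beta,gamma numeric coefficients, parallel to the index sets.
#' @slot mu numeric overall treatment effect.
#' @slot sigma positive error SD.
#' @slot cEff numeric effect-size multiplier used at generation.
#' @export
setClass("TrueModel",
  representation(
    p      = "integer",
    iBeta  = "integer",
    iGamma = "integer",
    beta   = "numeric",
    gamma  = "numeric",
    mu     = "numeric",
    sigma  = "numeric",
    cEff   = "numeric"
  )
)

setValidity("TrueModel", function(object) {
  msg <- character()
  if (length(object@beta) != length(object@iBeta))
    msg <- c(msg, "beta must be parallel to iBeta")
  if (length(object@gamma) != length(object@iGamma))
    msg <- c(msg, "gamma must be parallel to iGamma")
  if (anyDuplicated(object@iBeta) || anyDuplicated(object@iGamma))
    msg <- c(msg, "index sets must not contain duplicates")
  if (any(c(object@iBeta, object@iGamma) > object@p) ||
      any(c(object@iBeta, object@iGamma) < 1L))
    msg <- c(msg, "index sets must lie in 1..p")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: an estimated prognostic/predictive model
#'
#' The output of every selector (marginal tests, mBIC2, SLOBE, adaptive
#' lasso): estimated index sets with coefficients from the least-squares
#' refit of the reduced model, plus the fitted intercept and treatment
#' effect.
#'
#' @slot iBeta,iGamma integer SNP index sets (estimated).
#' @slot beta,gamma numeric fitted coefficients, parallel to the sets.
#' @slot muHat numeric fitted overall treatment effect.
#' @slot intercept numeric fitted intercept.
#' @slot method character tag identifying the selector.
#' @export
setClass("SelectionResult",
  representation(
    iBeta     = "integer",
    iGamma    = "integer",
    beta      = "numeric",
    gamma     = "numeric",
    muHat     = "numeric",
    intercept = "numeric",
    method    = "character"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@beta) != length(object@iBeta))
    msg <- c(msg, "beta must be parallel to iBeta")
  if (length(object@gamma) != length(object@iGamma))
    msg <- c(msg, "gamma must be parallel to iGamma")
  if (length(msg)) msg else TRUE
})

#' EfficacyOutcome: result of one treatment-efficacy testing strategy
#'
#' @slot method character, one of \code{"M1"}, \code{"M2"}, \code{"M2a"},
#'   \code{"M3"}, \code{"M4"}.
#' @slot reject logical, whether the strategy declares efficacy.
#' @slot pValues named numeric vector of component-test p-values.
#' @slot subgroupSize integer, size of the tested responder subgroup
#'   (methods 3 and 4; \code{NA} otherwise).
#' @slot subgroupDefined logical, whether a responder subgroup could be
#'   formed (i.e. at least one predictive marker was selected on the
#'   training half).
#' @export
setClass("EfficacyOutcome",
  representation(
    method          = "character",
    reject          = "logical",
    pValues         = "numeric",
    subgroupSize    = "integer",
    subgroupDefined = "logical"
  )
)
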