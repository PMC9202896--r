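#' @rdname SnpGenotypes-class
#' @param x an object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname SnpGenotypes-class
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname SnpGenotypes-class
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname SnpGenotypes-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname SnpGenotypes-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Extract the centered, unit-norm genotype value matrix
#' @param x a [StandardizedGenotypes-class].
#' @return numeric n x p matrix.
#' @export
setGeneric("stdValues", function(x) standardGeneric("stdValues"))

#' Extract the numeric 2p-column design matrix
#' @param x a [TrialDesign-class].
#' @return numeric n x 2p matrix; first p columns prognostic, last p
#'   predictive (genotype times treatment).
#' @export
setGeneric("designValues", function(x) standardGeneric("designValues"))

#' Treatment arm labels of a trial design
#' @param x a [TrialDesign-class].
#' @return numeric vector of -1/+1 arm labels.
#' @export
setGeneric("treatmentArm", function(x) standardGeneric("treatmentArm"))

#' @rdname SelectionResult-class
#' @param x a [SelectionResult-class].
#' @export
setGeneric("selectedPrognostic", function(x) standardGeneric("selectedPrognostic"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedPredictive", function(x) standardGeneric("selectedPredictive"))
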