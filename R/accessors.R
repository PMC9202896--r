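#' @rdname SnpGenotypes-class
#' @export
setMethod("dosages", "SnpGenotypes", function(x) x@dosages)

#' @rdname SnpGenotypes-class
#' @export
setMethod("mafs", "SnpGenotypes", function(x) x@mafs)

#' @rdname SnpGenotypes-class
#' @export
setMethod("clusterIds", "SnpGenotypes", function(x) x@clusterId)

#' @rdname StandardizedGenotypes-class
#' @export
setMethod("clusterIds", "StandardizedGenotypes", function(x) x@clusterId)

#' @rdname StandardizedGenotypes-class
#' @export
setMethod("mafs", "StandardizedGenotypes", function(x) x@mafs)

#' @rdname SnpGenotypes-class
#' @export
setMethod("snpIds", "SnpGenotypes", function(x) x@snpIds)

#' @rdname StandardizedGenotypes-class
#' @export
setMethod("snpIds", "StandardizedGenotypes", function(x) x@snpIds)

#' @rdname TrialDesign-class
#' @param x a TrialDesign.
#' @export
setMethod("snpIds", "TrialDesign", function(x) x@snpIds)

#' @rdname SnpGenotypes-class
#' @export
setMethod("sampleIds", "SnpGenotypes", function(x) x@sampleIds)

#' @rdname StandardizedGenotypes-class
#' @export
setMethod("sampleIds", "StandardizedGenotypes", function(x) x@sampleIds)

#' @rdname stdValues
#' @export
setMethod("stdValues", "StandardizedGenotypes", function(x) x@values)

#' @rdname designValues
#' @export
setMethod("designValues", "TrialDesign", function(x) x@values)

#' @rdname treatmentArm
#' @export
setMethod("treatmentArm", "TrialDesign", function(x) x@treatment)

#' @rdname SelectionResult-class
#' @export
setMethod("selectedPrognostic", "SelectionResult", function(x) x@iBeta)

#' @rdname SelectionResult-class
#' @export
setMethod("selectedPredictive", "SelectionResult", function(x) x@iGamma)

setMethod("show", "SnpGenotypes", function(object) {
  d <- dim(object@dosages)
  cat("SnpGenotypes:", d[1], "samples x", d[2], "SNPs\n")
  cat("  MAF range:", sprintf("%.3f - %.3f", min(object@mafs), max(object@mafs)), "\n")
  if (!is.null(object@clusterId))
    cat("  clusters:", length(unique(object@clusterId)), "\n")
})

setMethod("show", "StandardizedGenotypes", function(object) {
  d <- dim(object@values)
  cat("StandardizedGenotypes:", d[1], "samples x", d[2],
      "SNPs (zero mean, unit L2 norm)\n")
})

setMethod("show", "TrialDesign", function(object) {
  d <- dim(object@values)
  cat("TrialDesign:", d[1], "samples x", d[2], "columns",
      sprintf("(%d prognostic + %d predictive)\n",
              sum(object@roles == "prognostic"),
              sum(object@roles == "predictive")))
  tb <- table(factor(object@treatment, levels = c(-1, 1)))
  cat("  arms: control", tb[[1]], "/ treated", tb[[2]], "\n")
})

setMethod("show", "TrueModel", function(object) {
  cat("TrueModel: p =", object@p, "\n")
  cat("  prognostic SNPs:", length(object@iBeta),
      " predictive SNPs:", length(object@iGamma),
      " overlap:", length(intersect(object@iBeta, object@iGamma)), "\n")
  cat(sprintf("  mu = %g, sigma = %g, c_eff = %g\n",
              object@mu, object@sigma, object@cEff))
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult [", object@method, "]\n", sep = "")
  cat("  prognostic:", length(object@iBeta),
      " predictive:", length(object@iGamma), "\n")
  cat(sprintf("  muHat = %.4f\n", object@muHat))
})

setMethod("show", "EfficacyOutcome", function(object) {
  cat("EfficacyOutcome [", object@method, "]: ",
      if (object@reject) "REJECT" else "no rejection", "\n", sep = "")
  if (length(object@pValues))
    cat("  p-values:", paste(sprintf("%s=%.4g", names(object@pValues),
                                     object@pValues), collapse = ", "), "\n")
  if (!is.na(object@subgroupSize))
    cat("  subgroup size:", object@subgroupSize, "\n")
})
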