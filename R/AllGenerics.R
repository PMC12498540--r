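#' @name accessors
#' @title Accessors for riboMeth objects
#' @description Slot accessors for [EndCountProfile-class],
#'   [RRNAReferenceSet-class], [MethylationTable-class] and
#'   [StandardCurve-class] objects; use these rather than \code{@}.
#' @param x An object.
#' @return The slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("fivePrimeCounts", function(x) standardGeneric("fivePrimeCounts"))
#' @rdname accessors
#' @export
setGeneric("threePrimeCounts", function(x) standardGeneric("threePrimeCounts"))
#' @rdname accessors
#' @export
setGeneric("combinedCounts", function(x) standardGeneric("combinedCounts"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("referenceLength", function(x) standardGeneric("referenceLength"))
#' @rdname accessors
#' @export
setGeneric("methylationIndex", function(x) standardGeneric("methylationIndex"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setGeneric("curveEfficiency", function(x) standardGeneric("curveEfficiency"))

#' @rdname accessors
setMethod("moleculeId", "EndCountProfile", function(x) x@moleculeId)
#' @rdname accessors
setMethod("sampleId", "EndCountProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("fivePrimeCounts", "EndCountProfile", function(x) x@fivePrime)
#' @rdname accessors
setMethod("threePrimeCounts", "EndCountProfile", function(x) x@threePrime)
#' @rdname accessors
setMethod("combinedCounts", "EndCountProfile", function(x) x@combined)
#' @rdname accessors
setMethod("totalReads", "EndCountProfile", function(x) x@totalReads)
#' @rdname accessors
setMethod("referenceLength", "EndCountProfile", function(x) length(x@fivePrime))

#' @rdname accessors
setMethod("referenceLength", "RRNAReferenceSet",
  function(x) stats::setNames(Biostrings::width(x@sequences),
                              names(x@sequences)))
#' @rdname accessors
setMethod("moleculeId", "RRNAReferenceSet", function(x) names(x@sequences))

#' @rdname accessors
setMethod("methylationIndex", "MethylationTable",
  function(x) SummarizedExperiment::assay(x, "MI"))
#' @rdname accessors
setMethod("groupLabels", "MethylationTable",
  function(x) as.character(SummarizedExperiment::colData(x)$group))

#' @rdname accessors
setMethod("curveSlope", "StandardCurve", function(x) x@slope)
#' @rdname accessors
setMethod("curveEfficiency", "StandardCurve", function(x) x@efficiency)

setMethod("show", "RRNAReferenceSet", function(object) {
  cat("RRNAReferenceSet with", length(object@sequences), "molecule(s)\n")
  w <- Biostrings::width(object@sequences)
  for (i in seq_along(w))
    cat(sprintf("  %s: %d nt (%s)\n", names(object@sequences)[i], w[i],
                object@accessions[i]))
})

setMethod("show", "EndCountProfile", function(object) {
  cat(sprintf("EndCountProfile %s / %s: %d nt, %d reads\n",
              object@moleculeId, object@sampleId,
              length(object@fivePrime), object@totalReads))
  if (length(object@combined))
    cat(sprintf("  combined cleavage counts present (median %.0f)\n",
                stats::median(object@combined)))
  else cat("  combined counts not yet computed; run combineEndCounts()\n")
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve: Ct = %.4f * log10(dilution) + %.4f (R2 = %.4f, eff = %.1f%%)\n",
    object@slope, object@intercept, object@rSquared, 100 * object@efficiency))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(
    "SimulationTruth: L = %d, %d methylated site(s), rho = %.2f, N = %d, seed = %d\n",
    object@length, sum(object@methylation > 0), object@rho,
    object@nFragments, object@seed))
})
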