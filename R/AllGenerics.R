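#' @name accessors
#' @title Accessors for ppcgate classes
#' @description Accessor functions for the central data objects:
#' `activity()` returns the neurons-by-frames activity matrix,
#' `trials()` the trial table, `frameRate()` the acquisition rate,
#' `cellTypes()` the per-neuron labels, `groundTruth()` the planted
#' effect table of a synthetic session (or `NULL`), `axisWeights()` and
#' `axisKind()` the components of an [AxisModel-class], and
#' `modelDeltas()` the active-minus-passive population summaries of a
#' [SimResult-class].
#' @param x an object.
#' @return the component named by the accessor.
NULL

#' @rdname accessors
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))
#' @rdname accessors
#' @export
setMethod("activity", "PPCExperiment", function(x) assay(x, "activity"))

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "PPCExperiment", function(x) x@trials)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "PPCExperiment", function(x) x@frameRate)

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setMethod("cellTypes", "PPCExperiment",
          function(x) rowData(x)$cell_type)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "PPCExperiment",
          function(x) metadata(x)$ground_truth)

#' @rdname accessors
#' @export
setGeneric("axisWeights", function(x) standardGeneric("axisWeights"))
#' @rdname accessors
#' @export
setMethod("axisWeights", "AxisModel", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("axisKind", function(x) standardGeneric("axisKind"))
#' @rdname accessors
#' @export
setMethod("axisKind", "AxisModel", function(x) x@axisKind)

#' @rdname accessors
#' @export
setGeneric("modelDeltas", function(x) standardGeneric("modelDeltas"))

#' @rdname accessors
#' @export
setGeneric("modelSummary", function(x) standardGeneric("modelSummary"))
#' @rdname accessors
#' @export
setMethod("modelSummary", "SimResult", function(x) x@summary)

setMethod("show", "PPCExperiment", function(object) {
  callNextMethod()
  tr <- trials(object)
  cat(sprintf("trials(%d): %s\n", nrow(tr),
              paste(sprintf("%s=%d", names(table(tr$context)),
                            as.integer(table(tr$context))),
                    collapse = " ")))
  cat(sprintf("frameRate: %g Hz\n", frameRate(object)))
})

setMethod("show", "AxisModel", function(object) {
  cat(sprintf("AxisModel '%s' over %d neurons (fold %s)\n",
              object@axisKind, length(object@weights),
              ifelse(is.na(object@foldId), "-", object@foldId)))
})

setMethod("show", "NetworkParams", function(object) {
  cat(sprintf("NetworkParams: %d neurons (%s variant)\n",
              sum(object@sizes), object@variant))
  cat("  sizes:", paste(sprintf("%s=%d", names(object@sizes),
                                object@sizes), collapse = " "), "\n")
  cat(sprintf("  dt=%g ms, trial=%g ms, onset=%g ms, convention=%s\n",
              object@dt, object@trialMs, object@tOn,
              object@inputConvention))
})

setMethod("show", "NetworkRealization", function(object) {
  cat(sprintf(
    "NetworkRealization (%s): %d neurons, %d synapses, seed=%d\n",
    object@params@variant, nrow(object@J), length(object@J@x),
    object@seed))
  cat(sprintf("  context targets: %d, photostim targets: %d\n",
              length(object@contextTargets), length(object@photoTargets)))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %s variant, %d trials/condition, sides: %s\n",
              object@params@variant, object@nTrials,
              paste(object@sides, collapse = "+")))
  print(object@summary, row.names = FALSE)
})
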