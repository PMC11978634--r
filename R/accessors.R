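## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for circuit data objects
#' @description Slot accessors for the package's S4 classes.
#' @param object an S4 object from this package.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))
#' @rdname accessors
#' @export
setMethod("frameData", "EEGFrame", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("frameData", "SpectralFrame", function(object) object@amplitude)

#' @rdname accessors
#' @export
setGeneric("frameLabel", function(object) standardGeneric("frameLabel"))
#' @rdname accessors
#' @export
setMethod("frameLabel", "EEGFrame", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("frameLabel", "SpectralFrame", function(object) object@sourceLabel)

#' @rdname accessors
#' @export
setGeneric("decisionScore", function(object) standardGeneric("decisionScore"))
#' @rdname accessors
#' @export
setMethod("decisionScore", "Decision", function(object) object@score)

#' @rdname accessors
#' @export
setGeneric("decisionLabel", function(object) standardGeneric("decisionLabel"))
#' @rdname accessors
#' @export
setMethod("decisionLabel", "Decision", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("cycleCounts", function(object) standardGeneric("cycleCounts"))
#' @rdname accessors
#' @export
setMethod("cycleCounts", "CycleReport", function(object) object@cycles)

#' @rdname accessors
#' @export
setGeneric("totalCycles", function(object) standardGeneric("totalCycles"))
#' @rdname accessors
#' @export
setMethod("totalCycles", "CycleReport", function(object) sum(object@cycles))

#' @rdname accessors
#' @export
setGeneric("latencySeconds", function(object) standardGeneric("latencySeconds"))
#' @rdname accessors
#' @export
setMethod("latencySeconds", "CycleReport",
          function(object) sum(object@cycles) / object@clockHz)

#' @rdname accessors
#' @export
setGeneric("supportVectors", function(object) standardGeneric("supportVectors"))
#' @rdname accessors
#' @export
setMethod("supportVectors", "SVMModel", function(object) object@supportVectors)

#' @rdname accessors
#' @export
setGeneric("convLayers", function(object) standardGeneric("convLayers"))
#' @rdname accessors
#' @export
setMethod("convLayers", "CNNModel", function(object) object@layers)

#' @rdname accessors
#' @export
setGeneric("countsVector", function(object) standardGeneric("countsVector"))
#' @rdname accessors
#' @export
setMethod("countsVector", "ConfusionCounts", function(object)
  c(TP = object@TP, FP = object@FP, TN = object@TN, FN = object@FN))

setMethod("show", "EEGFrame", function(object) {
  cat(sprintf("EEGFrame: %d channels x %d samples at %g Hz, label = %s\n",
              nrow(object@data), ncol(object@data), object@sampleRateHz,
              if (is.na(object@label)) "unlabelled"
              else if (object@label == 1L) "ictal" else "interictal"))
})

setMethod("show", "SpectralFrame", function(object) {
  cat(sprintf("SpectralFrame: %d x %d amplitude spectrum, max %.4g\n",
              nrow(object@amplitude), ncol(object@amplitude), max(object@amplitude)))
})

setMethod("show", "CNNModel", function(object) {
  ks <- vapply(object@layers, function(l) nrow(l@weights), integer(1))
  cat(sprintf("CNNModel: conv kernels %s; activations %s\n",
              paste(sprintf("%dx%d", ks, ks), collapse = " -> "),
              paste(vapply(object@layers, function(l) l@activation, character(1)),
                    collapse = ", ")))
})

setMethod("show", "SVMModel", function(object) {
  cat(sprintf(paste0("SVMModel: %d support vectors (k = %d), gammaEff = %.6g, ",
                     "b = %.6g, log transform %s\n"),
              nrow(object@supportVectors), ncol(object@supportVectors),
              object@gammaEff, object@b,
              if (object@logTransform) "on" else "off"))
})

setMethod("show", "Decision", function(object) {
  cat(sprintf("Decision: %s (score %.6g)\n", object@label, object@score))
})

setMethod("show", "CycleReport", function(object) {
  cat(sprintf("CycleReport: %d cycles total = %.4g ms at %.3g MHz\n",
              as.integer(sum(object@cycles)),
              1e3 * sum(object@cycles) / object@clockHz, object@clockHz / 1e6))
  print(object@cycles)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (ictal positive)\n",
              object@TP, object@FP, object@TN, object@FN))
})
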