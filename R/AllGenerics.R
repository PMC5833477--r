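#' Accessors for gate, fit and screen objects
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `gateCutoff()` returns the intensity cutoff in a.u., `gateK()` the SD
#' multiplier, `gateStats()` the control statistics the cutoff was derived
#' from; `ic50()`, `hillSlope()` and `isConverged()` read a
#' [DoseResponseFit-class]; `screenWells()` and `plateQC()` read a
#' [ScreenResult-class].
#'
#' @param object the object to read from.
#' @return See the individual methods; scalars for cutoff/IC50 style
#'   accessors, a named list for `gateStats()` and `plateQC()`, a
#'   data.frame for `screenWells()`.
#' @name accessors
#' @examples
#' g <- computeGateThreshold(c(8, 10, 12), k = 6, minCells = 1)
#' gateCutoff(g)
#' gateStats(g)
NULL

#' @rdname accessors
#' @export
setGeneric("gateCutoff", function(object) standardGeneric("gateCutoff"))

#' @rdname accessors
#' @export
setGeneric("gateK", function(object) standardGeneric("gateK"))

#' @rdname accessors
#' @export
setGeneric("gateStats", function(object) standardGeneric("gateStats"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("screenWells", function(object) standardGeneric("screenWells"))

#' @rdname accessors
#' @export
setGeneric("plateQC", function(object) standardGeneric("plateQC"))

#' @rdname accessors
#' @export
setMethod("gateCutoff", "GateThreshold", function(object) object@threshold)

#' @rdname accessors
#' @export
setMethod("gateK", "GateThreshold", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("gateStats", "GateThreshold", function(object) {
  list(
    mean = object@meanDeab, sd = object@sdDeab, k = object@k,
    threshold = object@threshold, nControlCells = object@nControlCells,
    sourceWells = object@sourceWells
  )
})

#' @rdname accessors
#' @export
setMethod("ic50", "DoseResponseFit", function(object) object@ic50)

#' @rdname accessors
#' @export
setMethod("hillSlope", "DoseResponseFit", function(object) object@hill)

#' @rdname accessors
#' @export
setMethod("isConverged", "DoseResponseFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("screenWells", "ScreenResult", function(object) object@wells)

#' @rdname accessors
#' @export
setMethod("plateQC", "ScreenResult", function(object) {
  list(
    rzPrime = object@rzPrime,
    signalToBackground = object@signalToBackground,
    nMasked = sum(object@wells$masked, na.rm = TRUE),
    nHits = sum(object@wells$hit, na.rm = TRUE)
  )
})
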