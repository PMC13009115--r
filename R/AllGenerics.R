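#' @include AllClasses.R
NULL

#' Extract the per-segment bullseye from an activation map
#'
#' @param x an \linkS4class{ECGIMap}, \linkS4class{IsochroneMap} or a
#'   data.frame of samples with columns \code{segment}, \code{at} and
#'   (for EWI epicardial restriction) \code{wallDepth}.
#' @param model the segment model from \code{\link{buildSegmentModel}}.
#' @param ... method-specific arguments.
#' @return a \linkS4class{SegmentBullseye}.
#' @export
setGeneric("extractBullseye", function(x, model, ...)
  standardGeneric("extractBullseye"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("activationTimes", function(x) standardGeneric("activationTimes"))

#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname accessors
#' @export
setGeneric("wallDepth", function(x) standardGeneric("wallDepth"))

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname accessors
#' @export
setGeneric("egmSamples", function(x) standardGeneric("egmSamples"))

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("bullseyeValues", function(x) standardGeneric("bullseyeValues"))
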