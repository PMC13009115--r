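#' @include isochrone.R
NULL

#' Co-register views on a common ECG clock
#'
#' Re-expresses every view's activation times relative to its own surface
#' ECG reference event — QRS onset for spontaneous beats, the pacing spike
#' for paced beats — so all views share a common timing reference. Each
#' map's applied offset is recorded in its \code{offset} slot.
#'
#' @param views list of \code{list(map = IsochroneMap, ecg = ECGTrace)}.
#' @return list of re-referenced \linkS4class{IsochroneMap}s.
#' @export
registerViews <- function(views) {
  if (!length(views)) stop("no views supplied")
  lapply(views, function(v) {
    ref <- if (v$ecg@beatType == "paced" && !is.na(v$ecg@pacingSpike))
      v$ecg@pacingSpike else v$ecg@qrsOnset
    if (is.na(ref))
      stop("view without a QRS onset or pacing spike cannot be registered")
    m <- v$map
    m@at <- m@at - ref
    m@offset <- m@offset + ref
    m
  })
}
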