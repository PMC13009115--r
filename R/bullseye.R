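#' @include segments.R AllGenerics.R egm.R
NULL

bullseyeFromSamples <- function(segment, at, model, modality, subject) {
  vals <- stats::setNames(rep(NA_real_, nrow(model)), model$segment)
  ok <- segment %in% model$segment & !is.na(at)
  if (any(ok)) {
    m <- tapply(at[ok], segment[ok], mean)
    vals[names(m)] <- as.numeric(m)
  }
  empty <- if (modality == "ECGI")
    model$segment[model$ecgiCovered & is.na(vals)]
  else model$segment[is.na(vals)]
  if (length(empty))
    warning(modality, " bullseye: segment(s) with no samples masked: ",
      paste(empty, collapse = ", "))
  new("SegmentBullseye", values = vals, modality = modality,
    subject = subject)
}

#' @describeIn extractBullseye samples table with columns \code{segment},
#'   \code{at} and, for the EWI epicardial restriction, \code{wallDepth}
#'   (only samples with wall depth >= 2/3 enter an EWI bullseye).
#' @param modality "EWI" (restricted to epicardial-layer samples) or "ECGI".
#' @param subject subject identifier carried into the bullseye.
#' @export
setMethod("extractBullseye", signature(x = "data.frame"),
  function(x, model, modality = "EWI", subject = NA_character_, ...) {
    stopifnot(all(c("segment", "at") %in% names(x)))
    if (modality == "EWI" && "wallDepth" %in% names(x))
      x <- x[!is.na(x$wallDepth) & x$wallDepth >= 2 / 3, , drop = FALSE]
    bullseyeFromSamples(x$segment, x$at, model, modality, subject)
  })

#' @describeIn extractBullseye epicardial activation times of an isochrone
#'   map: per-segment mean over mask pixels with wall depth >= 2/3.
#' @export
setMethod("extractBullseye", signature(x = "IsochroneMap"),
  function(x, model, modality = "EWI", subject = NA_character_, ...) {
    msk <- x@mask
    idx <- which(msk@mask & msk@segmentIdx > 0)
    df <- data.frame(
      segment = msk@segmentLabels[msk@segmentIdx[idx]],
      at = x@at[idx], wallDepth = msk@wallDepth[idx])
    extractBullseye(df, model, modality = modality, subject = subject)
  })

#' @describeIn extractBullseye ECGI map: per-segment mean of node LATs,
#'   recomputed from the stored electrograms with \code{\link{computeLAT}}
#'   (set \code{recompute = FALSE} to use the stored annotations); septal
#'   segments are masked by coverage.
#' @param recompute logical; recompute node LATs from the electrograms.
#' @export
setMethod("extractBullseye", signature(x = "ECGIMap"),
  function(x, model, recompute = TRUE, subject = x@subject, ...) {
    lat <- if (recompute)
      vapply(x@uegms, computeLAT, numeric(1)) else x@nodes$lat
    bullseyeFromSamples(x@nodes$segment, lat, model, "ECGI", subject)
  })
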