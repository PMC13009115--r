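#' @include register.R
NULL

#' Localize the site of origin across co-registered views
#'
#' The site of origin is the site of earliest activation in any view after
#' co-registration. The earliest region is the set of pixels within
#' \code{earlyWindowMs} (default 5 ms) of the global minimum activation time
#' across all views; the anatomical SoO is the segment containing the
#' AT-weighted centroid of that region in the view attaining the minimum,
#' and the axial SoO is the wall-depth tercile (endo / mid / epi) at that
#' centroid. A map is flagged diffuse — and its axial call set to "diffuse"
#' — when the earliest region spreads over more than \code{maxSegments}
#' segments or more than \code{maxFraction} of any view's mask while the
#' near-minimum set (within \code{uniqueTolMs} of the minimum) is not
#' confined to a single segment of a single view.
#'
#' @param views list of registered \linkS4class{IsochroneMap}s.
#' @param earlyWindowMs early-region window above the global minimum (ms).
#' @param maxSegments diffuse threshold on the segment span (default 2).
#' @param maxFraction diffuse threshold on the mask fraction (default 0.25).
#' @param uniqueTolMs tolerance defining the near-minimum set (default 1).
#' @return a \linkS4class{SoOEstimate}.
#' @export
localizeSoO <- function(views, earlyWindowMs = 5, maxSegments = 2,
                        maxFraction = 0.25, uniqueTolMs = 1) {
  if (!length(views)) stop("no views supplied")
  mins <- vapply(views, function(m) min(m@at[m@mask@mask], na.rm = TRUE),
    numeric(1))
  vmin <- which.min(mins)
  gmin <- mins[vmin]

  segsEarly <- character(0); segsNear <- character(0)
  fracs <- numeric(length(views)); nearViews <- 0L
  for (k in seq_along(views)) {
    m <- views[[k]]
    idx <- which(m@mask@mask)
    a <- m@at[idx]
    early <- a <= gmin + earlyWindowMs
    near <- a <= gmin + uniqueTolMs
    fracs[k] <- mean(early)
    si <- m@mask@segmentIdx[idx]
    lab <- ifelse(si > 0, m@mask@segmentLabels[pmax(si, 1L)], "unassigned")
    segsEarly <- union(segsEarly, lab[early])
    segsNear <- union(segsNear, lab[near])
    if (any(near)) nearViews <- nearViews + 1L
  }
  uniqueMin <- nearViews == 1L && length(segsNear) == 1L
  diffuse <- (length(segsEarly) > maxSegments || any(fracs > maxFraction)) &&
    !uniqueMin

  m <- views[[vmin]]
  idx <- which(m@mask@mask)
  a <- m@at[idx]
  early <- which(a <= gmin + earlyWindowMs)
  co <- maskCoords(m@mask, idx[early])
  w <- (gmin + earlyWindowMs - a[early]) + 1e-9
  cx <- sum(w * co$x) / sum(w); cy <- sum(w * co$y) / sum(w)
  cpix <- early[which.min((co$x - cx)^2 + (co$y - cy)^2)]
  si <- m@mask@segmentIdx[idx[cpix]]
  segment <- if (si > 0) m@mask@segmentLabels[si] else "unassigned"
  layer <- if (diffuse) "diffuse"
    else layerOfDepth(m@mask@wallDepth[idx[cpix]])
  viewName <- if (!is.null(m@mask@geometry)) m@mask@geometry@viewName
    else as.character(vmin)
  new("SoOEstimate", segment = segment, layer = layer,
    earliestTime = gmin, diffuse = diffuse, view = viewName)
}

#' Map one view end to end: strain movie to isochrone map
#'
#' Convenience wrapper for the per-view mapping chain: sample recording
#' points, detect zero crossings, interpolate isochrones. Activation times
#' stay on the acquisition clock; \code{\link{registerViews}} subtracts the
#' ECG reference afterwards.
#'
#' @param movie a \linkS4class{StrainMovie} whose sites cover the mask.
#' @param n number of recording points (default 250).
#' @param seed seed for point sampling.
#' @param overrides optional manual-override table (pixel, at).
#' @param ... passed to \code{\link{detectZeroCrossing}}.
#' @return list with \code{map} (\linkS4class{IsochroneMap}), \code{ecg},
#'   and the annotated \code{points} table.
#' @export
mapView <- function(movie, n = 250, seed = NULL, overrides = NULL, ...) {
  if (is.null(movie@mask)) stop("movie carries no mask")
  pts <- samplePoints(movie@mask, n, "stratified", seed = seed)
  keep <- match(pts$pixel, movie@sites$pixel)
  if (anyNA(keep)) stop("sampled points missing from the movie's sites")
  sub <- new("StrainMovie", frames = movie@frames[, keep, drop = FALSE],
    frameRate = movie@frameRate, startMs = movie@startMs,
    sites = movie@sites[keep, ], mask = movie@mask, ecg = movie@ecg)
  qrs <- movie@ecg@qrsOnset
  ann <- annotateZeroCrossings(sub, reference = 0,
    window = c(qrs, min(qrs + 350,
      movie@startMs + 1000 * (nrow(movie@frames) - 1) / movie@frameRate)),
    overrides = overrides, ...)
  ok <- !is.na(ann$at)
  map <- interpolateIsochrones(ann[ok, c("x", "y", "at")], movie@mask)
  list(map = map, ecg = movie@ecg, points = ann)
}
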