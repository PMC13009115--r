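#' @include mask.R
NULL

#' Sample recording points in a myocardial mask
#'
#' Emulates the manual selection of 150-300 recording sites per view:
#' either uniformly at random over mask pixels or stratified by segment with
#' exact largest-remainder proportional allocation to segment areas.
#'
#' @param mask a \linkS4class{MyocardialMask}.
#' @param n number of points (>= 3; Delaunay interpolation needs at least
#'   3 non-collinear points).
#' @param strategy "uniform" or "stratified".
#' @param seed optional integer seed.
#' @return data.frame with columns pixel (linear index), row, col, x, y.
#' @export
samplePoints <- function(mask, n, strategy = c("uniform", "stratified"),
                         seed = NULL) {
  strategy <- match.arg(strategy)
  if (n < 3) stop("need at least 3 points")
  idx <- which(mask@mask)
  if (n > length(idx)) stop("n exceeds the mask pixel count")
  pick <- function() {
    if (strategy == "uniform") return(sort(sample(idx, n)))
    segs <- mask@segmentIdx[idx]
    labeled <- idx[segs > 0]
    segL <- segs[segs > 0]
    areas <- table(segL)
    alloc <- allocateProportional(n, as.numeric(areas))
    out <- unlist(lapply(seq_along(areas), function(k) {
      pool <- labeled[segL == as.integer(names(areas)[k])]
      sample(pool, min(alloc[k], length(pool)))
    }))
    sort(out)
  }
  pts <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  cbind(data.frame(pixel = pts), maskCoords(mask, pts))
}
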