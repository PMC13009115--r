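#' @include mask.R
NULL

#' Construct a focal source specification
#'
#' @param segment segment label of the source.
#' @param layer transmural layer: "endo", "mid" or "epi".
#' @param originTime onset time in ms relative to the timing reference.
#' @param cv conduction velocity in mm/ms (default 0.8).
#' @param scar list of \code{list(poly = n x 2 mm matrix, mult)} slow regions.
#' @return a \linkS4class{SourceSpec}.
#' @export
sourceSpec <- function(segment, layer = "endo", originTime = 10, cv = 0.8,
                       scar = list()) {
  new("SourceSpec", segment = segment, layer = layer,
    originTime = originTime, cv = cv, scar = scar)
}

#' Simulate a focal activation field by geodesic wavefront propagation
#'
#' Electrical activation time at each mask pixel is the source onset time
#' plus the geodesic distance from the source through the myocardium,
#' travelled at the local conduction velocity. Distances are shortest paths
#' (Dijkstra) on the 8-connected pixel adjacency graph with metric edge
#' lengths; an edge's traversal time is its length times the mean slowness
#' (1/velocity) of its endpoints. Scar polygons scale the local velocity by
#' their multiplier.
#'
#' The source pixel is the mask pixel nearest the centroid of the source
#' region (source segment intersected with the source layer's wall-depth
#' tercile), unless \code{sourcePixel} is given explicitly.
#'
#' @param mask a \linkS4class{MyocardialMask}.
#' @param source a \linkS4class{SourceSpec}.
#' @param sourcePixel optional c(row, col) overriding segment/layer placement.
#' @return an \linkS4class{ActivationField}; pixels unreachable from the
#'   source carry NA activation times (with a warning).
#' @examples
#' m <- buildStripMask(20, 5, spacing = 1)
#' f <- simulateActivation(m, sourceSpec("S1", cv = 1), sourcePixel = c(3, 1))
#' @export
simulateActivation <- function(mask, source, sourcePixel = NULL) {
  idx <- which(mask@mask)
  n <- length(idx)
  if (n == 0L) stop("empty mask")
  dm <- dim(mask@mask)
  rc <- arrayInd(idx, dm)
  co <- maskCoords(mask, idx)

  # local conduction velocity, with scar multipliers
  v <- rep(source@cv, n)
  for (s in source@scar) {
    ins <- pointInPolygon(co$x, co$y, s$poly)
    v[ins] <- v[ins] * s$mult
  }

  # source region: segment x layer tercile
  if (is.null(sourcePixel)) {
    segI <- match(source@segment, mask@segmentLabels)
    if (is.na(segI)) stop("source region does not intersect the mask: ",
      "unknown segment '", source@segment, "'")
    wd <- mask@wallDepth[idx]
    inLayer <- layerOfDepth(wd) == source@layer
    region <- which(mask@segmentIdx[idx] == segI & inLayer)
    if (!length(region))
      stop("source region does not intersect the mask")
    cx <- mean(co$x[region]); cy <- mean(co$y[region])
    src <- region[which.min((co$x[region] - cx)^2 + (co$y[region] - cy)^2)]
  } else {
    src <- which(rc[, 1] == sourcePixel[1] & rc[, 2] == sourcePixel[2])
    if (!length(src)) stop("source pixel is not inside the mask")
  }

  # 8-connected pixel graph with metric edge lengths
  lut <- matrix(NA_integer_, dm[1], dm[2])
  lut[idx] <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rc[, 1] + off[1]; c2 <- rc[, 2] + off[2]
    ok <- r2 >= 1L & r2 <= dm[1] & c2 >= 1L & c2 <= dm[2]
    j <- rep(NA_integer_, n)
    j[ok] <- lut[cbind(r2[ok], c2[ok])]
    keep <- !is.na(j)
    if (!any(keep)) next
    i <- seq_len(n)[keep]; j <- j[keep]
    len <- mask@spacing * sqrt(sum(off^2))
    from <- c(from, i); to <- c(to, j)
    w <- c(w, len * 0.5 * (1 / v[i] + 1 / v[j]))
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  d <- as.numeric(igraph::distances(g, v = src, weights = w,
    algorithm = "dijkstra"))

  at <- matrix(NA_real_, dm[1], dm[2])
  at[idx] <- source@originTime + d
  if (any(is.infinite(d))) {
    warning("mask component(s) unreachable from the source: ",
      sum(is.infinite(d)), " pixel(s) flagged with undefined AT")
    at[idx[is.infinite(d)]] <- NA_real_
  }
  new("ActivationField", at = at, mask = mask, source = source)
}
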