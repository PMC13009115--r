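#' @include geometry.R utils.R
NULL

#' Build a myocardial mask for a sector view
#'
#' Rasterizes a half-annular wall (concentric endocardial and epicardial
#' contours centered on the sector apex) onto a Cartesian grid, computes the
#' normalized transmural coordinate (0 at the endocardial contour, 1 at the
#' epicardial contour) and divides the angular span equally among the
#' requested segment labels. This emulates the manually segmented ventricular
#' myocardium of a B-mode view.
#'
#' @param geometry a \linkS4class{ViewGeometry}.
#' @param rEndo endocardial contour radius in mm.
#' @param rEpi epicardial contour radius in mm (> rEndo).
#' @param spacing raster pixel size in mm (default 0.5).
#' @param segments character vector of segment labels spread equally over
#'   the angular span (first label at the most negative angle).
#' @return a \linkS4class{MyocardialMask}.
#' @examples
#' m <- buildMask(viewGeometry(depthMax = 50), rEndo = 30, rEpi = 40)
#' range(wallDepth(m), na.rm = TRUE)
#' @export
buildMask <- function(geometry, rEndo = 30, rEpi = 40, spacing = 0.5,
                      segments = paste0("S", 1:4)) {
  if (rEpi <= rEndo)
    stop("degenerate contours: epicardial radius must exceed endocardial")
  if (rEpi > geometry@depthMax)
    stop("contours must lie inside the sector (rEpi > depthMax)")
  half <- geometry@sectorAngle / 2
  ax <- geometry@apex[1]; ay <- geometry@apex[2]
  xr <- rEpi * sin(half * pi / 180) + spacing
  xs <- seq(ax - xr, ax + xr, by = spacing)
  ys <- seq(ay, ay + rEpi + spacing, by = spacing)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  r <- sqrt((X - ax)^2 + (Y - ay)^2)
  ang <- atan2(X - ax, Y - ay) * 180 / pi
  inside <- r >= rEndo & r <= rEpi & ang >= -half & ang <= half
  wd <- matrix(NA_real_, nrow(inside), ncol(inside))
  wd[inside] <- (r[inside] - rEndo) / (rEpi - rEndo)
  seg <- matrix(NA_integer_, nrow(inside), ncol(inside))
  nseg <- length(segments)
  segOf <- pmin(nseg, pmax(1L, 1L + floor((ang + half) / (2 * half) * nseg)))
  seg[inside] <- segOf[inside]
  new("MyocardialMask", mask = inside, wallDepth = wd, segmentIdx = seg,
    segmentLabels = segments, spacing = spacing,
    origin = c(xs[1], ys[1]), geometry = geometry)
}

#' Build a rectangular strip mask
#'
#' A simple straight-strip myocardium (useful for closed-form propagation
#' checks): \code{lengthMm} long, \code{widthMm} thick, wall depth running
#' across the width.
#'
#' @param lengthMm strip length in mm.
#' @param widthMm strip thickness in mm.
#' @param spacing pixel size in mm.
#' @param segments segment labels spread equally along the length.
#' @return a \linkS4class{MyocardialMask}.
#' @export
buildStripMask <- function(lengthMm = 40, widthMm = 8, spacing = 0.5,
                           segments = "S1") {
  xs <- seq(0, lengthMm, by = spacing)
  ys <- seq(0, widthMm, by = spacing)
  msk <- matrix(TRUE, length(ys), length(xs))
  wd <- matrix(rep(ys / widthMm, length(xs)), length(ys), length(xs))
  nseg <- length(segments)
  sg <- pmin(nseg, 1L + floor(xs / (lengthMm + 1e-9) * nseg))
  seg <- matrix(rep(as.integer(sg), each = length(ys)), length(ys), length(xs))
  new("MyocardialMask", mask = msk, wallDepth = wd, segmentIdx = seg,
    segmentLabels = segments, spacing = spacing, origin = c(0, 0),
    geometry = NULL)
}
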