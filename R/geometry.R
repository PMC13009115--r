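#' @include AllClasses.R
NULL

#' Construct a view geometry
#'
#' @param viewName view label ("4ch", "5ch", "3.5ch", "3ch", "2ch", "RVIT"
#'   or custom).
#' @param nLines number of scan lines (default 128).
#' @param sectorAngle sector opening angle in degrees (default 90).
#' @param depthSamples samples per line.
#' @param depthMax maximum depth in mm.
#' @param apex (x, y) apex position in mm.
#' @param frameRate frames per second (default 2000).
#' @return a \linkS4class{ViewGeometry}.
#' @examples
#' viewGeometry("4ch")
#' @export
viewGeometry <- function(viewName = "4ch", nLines = 128L, sectorAngle = 90,
                         depthSamples = 256L, depthMax = 120,
                         apex = c(0, 0), frameRate = 2000) {
  new("ViewGeometry", viewName = viewName, nLines = as.integer(nLines),
    sectorAngle = sectorAngle, depthSamples = as.integer(depthSamples),
    depthMax = depthMax, apex = as.numeric(apex), frameRate = frameRate)
}

#' Temporal resolution of a frame rate
#'
#' The temporal resolution of an activation map is one frame period:
#' 1000 / frameRate ms. At 2000 fps this is 0.5 ms.
#'
#' @param frameRate frames per second.
#' @return frame period in ms.
#' @examples
#' temporalResolution(2000) # 0.5 ms
#' @export
temporalResolution <- function(frameRate) {
  stopifnot(frameRate > 0)
  1000 / frameRate
}

#' Axial RF sample spacing
#'
#' Axial spacing of beamformed RF samples: c / (2 fs), the two-way
#' travel-distance per sample. With c = 1540 m/s and fs = 20 MHz the spacing
#' (and hence the attainable axial resolution of sample-resolved tracking)
#' is 0.0385 mm.
#'
#' @param c speed of sound in m/s (default 1540).
#' @param fs RF sampling rate in Hz (default 20 MHz).
#' @return axial sample spacing in mm.
#' @examples
#' axialSampleSpacing() # 0.0385 mm
#' @export
axialSampleSpacing <- function(c = 1540, fs = 20e6) {
  stopifnot(c > 0, fs > 0)
  c / (2 * fs) * 1000
}

#' Polar-to-Cartesian mapping of a sector geometry
#'
#' Maps (line index, depth) polar scan coordinates to Cartesian mm
#' coordinates. Lines fan symmetrically about the downward (+y) axis from
#' the apex. The mapping is bijective on the sector.
#'
#' @param geometry a \linkS4class{ViewGeometry}.
#' @param line line index (1..nLines), may be fractional.
#' @param depthMm depth along the line in mm.
#' @return data.frame with x, y (mm) and the line angle in degrees.
#' @export
polarToCartesian <- function(geometry, line, depthMm) {
  half <- geometry@sectorAngle / 2
  ang <- -half + (line - 1) / (geometry@nLines - 1) * geometry@sectorAngle
  th <- ang * pi / 180
  data.frame(x = geometry@apex[1] + depthMm * sin(th),
             y = geometry@apex[2] + depthMm * cos(th),
             angleDeg = ang)
}
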