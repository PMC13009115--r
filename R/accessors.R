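#' @include AllGenerics.R
NULL

#' Accessors for ewimap containers
#'
#' Small accessor functions for the central S4 containers: frame rates,
#' activation-time images, mask grids, transmural depth, segment labels,
#' electrogram samples, node tables and bullseye values.
#'
#' @param x an ewimap object.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("frameRate", "StrainMovie", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "ViewGeometry", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "RFFrames", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("activationTimes", "ActivationField", function(x) x@at)

#' @rdname accessors
#' @export
setMethod("activationTimes", "IsochroneMap", function(x) x@at)

#' @rdname accessors
#' @export
setMethod("maskGrid", "MyocardialMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("wallDepth", "MyocardialMask", function(x) x@wallDepth)

#' @rdname accessors
#' @export
setMethod("segmentLabels", "MyocardialMask", function(x) x@segmentLabels)

#' @rdname accessors
#' @export
setMethod("egmSamples", "UnipolarEGM", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("nodeTable", "ECGIMap", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("bullseyeValues", "SegmentBullseye", function(x) x@values)

#' Pixel-center coordinates of a mask raster
#'
#' @param mask a \linkS4class{MyocardialMask}.
#' @param idx optional linear (column-major) pixel indices; default all mask
#'   pixels.
#' @return data.frame with columns row, col, x, y (mm).
#' @export
maskCoords <- function(mask, idx = which(mask@mask)) {
  rc <- arrayInd(idx, dim(mask@mask))
  data.frame(row = rc[, 1], col = rc[, 2],
    x = mask@origin[1] + (rc[, 2] - 1) * mask@spacing,
    y = mask@origin[2] + (rc[, 1] - 1) * mask@spacing)
}

#' Transmural layer of a normalized wall depth
#'
#' Terciles of the normalized transmural coordinate define the layers:
#' endo [0, 1/3), mid [1/3, 2/3), epi [2/3, 1].
#'
#' @param depth numeric vector in [0, 1].
#' @return character vector of "endo", "mid", "epi".
#' @export
layerOfDepth <- function(depth) {
  out <- ifelse(depth < 1 / 3, "endo", ifelse(depth < 2 / 3, "mid", "epi"))
  out[is.na(depth)] <- NA_character_
  out
}
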