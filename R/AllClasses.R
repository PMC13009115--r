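#' @import methods
NULL

#' Scan geometry of a single echocardiographic view
#'
#' Describes the polar acquisition geometry of one high-frame-rate 2D view:
#' number of scan lines, sector opening angle, imaging depth and frame rate.
#' Defaults correspond to a 128-line, 90-degree sector acquired at 2000
#' frames per second.
#'
#' @slot viewName single character, e.g. "4ch", "2ch", "RVIT".
#' @slot nLines integer, number of scan lines across the sector.
#' @slot sectorAngle numeric, sector opening angle in degrees (0, 180].
#' @slot depthSamples integer, number of samples along each line.
#' @slot depthMax numeric, maximum imaging depth in mm.
#' @slot apex numeric(2), (x, y) position of the sector apex in mm.
#' @slot frameRate numeric, frames per second.
#' @exportClass ViewGeometry
setClass("ViewGeometry",
  representation(viewName = "character", nLines = "integer",
    sectorAngle = "numeric", depthSamples = "integer", depthMax = "numeric",
    apex = "numeric", frameRate = "numeric"),
  prototype(viewName = "4ch", nLines = 128L, sectorAngle = 90,
    depthSamples = 256L, depthMax = 120, apex = c(0, 0), frameRate = 2000))

setValidity("ViewGeometry", function(object) {
  msg <- NULL
  if (length(object@viewName) != 1L) msg <- c(msg, "viewName must be length 1")
  if (object@nLines < 2L) msg <- c(msg, "nLines must be >= 2")
  if (object@sectorAngle <= 0 || object@sectorAngle > 180)
    msg <- c(msg, "sectorAngle must be in (0, 180]")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@depthMax <= 0) msg <- c(msg, "depthMax must be > 0")
  if (length(object@apex) != 2L) msg <- c(msg, "apex must be length 2")
  if (is.null(msg)) TRUE else msg
})

#' Myocardial mask on a Cartesian raster
#'
#' Boolean myocardium mask on the Cartesian raster of a view, together with
#' a per-pixel normalized transmural coordinate (0 = endocardium,
#' 1 = epicardium) and a per-pixel segment label index into the 24-segment
#' model (0 = unassigned).
#'
#' @slot mask logical matrix; TRUE on myocardium.
#' @slot wallDepth numeric matrix in [0, 1] on mask pixels, NA elsewhere.
#' @slot segmentIdx integer matrix; index into \code{segmentLabels}, 0 for
#'   in-mask pixels without a segment assignment, NA outside the mask.
#' @slot segmentLabels character vector of segment labels.
#' @slot spacing numeric, pixel spacing in mm (isotropic).
#' @slot origin numeric(2), (x, y) of the center of pixel [1, 1] in mm.
#' @slot geometry the \linkS4class{ViewGeometry} the raster belongs to, or NULL.
#' @exportClass MyocardialMask
setClass("MyocardialMask",
  representation(mask = "matrix", wallDepth = "matrix",
    segmentIdx = "matrix", segmentLabels = "character", spacing = "numeric",
    origin = "numeric", geometry = "ANY"))

setValidity("MyocardialMask", function(object) {
  msg <- NULL
  d <- dim(object@mask)
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!identical(dim(object@wallDepth), d))
    msg <- c(msg, "wallDepth dimensions must match mask")
  if (!identical(dim(object@segmentIdx), d))
    msg <- c(msg, "segmentIdx dimensions must match mask")
  wd <- object@wallDepth[object@mask]
  if (anyNA(wd)) msg <- c(msg, "wallDepth must be defined on all mask pixels")
  else if (length(wd) && (min(wd) < 0 || max(wd) > 1))
    msg <- c(msg, "wallDepth must lie in [0, 1] on mask pixels")
  if (anyNA(object@segmentIdx[object@mask]))
    msg <- c(msg, "segmentIdx must be defined (0 = unassigned) on mask pixels")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must be length 2")
  if (is.null(msg)) TRUE else msg
})

#' Focal source specification
#'
#' Ground-truth description of a focal wavefront source: the segment and
#' transmural layer it starts in, its onset time relative to the timing
#' reference, the conduction velocity, and optional slow-conducting scar
#' regions (polygons with a velocity multiplier).
#'
#' @slot segment character, segment label of the source.
#' @slot layer one of "endo", "mid", "epi".
#' @slot originTime numeric, onset time in ms (may be negative, pre-QRS).
#' @slot cv numeric, conduction velocity in mm/ms.
#' @slot scar list of \code{list(poly = n x 2 matrix (mm), mult = numeric)}
#'   with velocity multipliers in (0, 1].
#' @exportClass SourceSpec
setClass("SourceSpec",
  representation(segment = "character", layer = "character",
    originTime = "numeric", cv = "numeric", scar = "list"),
  prototype(segment = NA_character_, layer = "endo", originTime = 10,
    cv = 0.8, scar = list()))

setValidity("SourceSpec", function(object) {
  msg <- NULL
  if (!object@layer %in% c("endo", "mid", "epi"))
    msg <- c(msg, "layer must be one of endo/mid/epi")
  if (object@cv <= 0) msg <- c(msg, "conduction velocity must be > 0")
  for (s in object@scar) {
    if (!is.list(s) || is.null(s$poly) || is.null(s$mult))
      msg <- c(msg, "each scar entry needs $poly and $mult")
    else if (s$mult <= 0 || s$mult > 1)
      msg <- c(msg, "scar velocity multipliers must be in (0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Electrical activation field
#'
#' Per-pixel electrical activation time (ms relative to QRS onset or pacing
#' spike) on a myocardial mask, with the ground-truth source that generated
#' it. Pixels unreachable from the source carry NA.
#'
#' @slot at numeric matrix of activation times (ms), NA outside the mask and
#'   on unreachable pixels.
#' @slot mask the \linkS4class{MyocardialMask}.
#' @slot source the \linkS4class{SourceSpec} ground truth.
#' @exportClass ActivationField
setClass("ActivationField",
  representation(at = "matrix", mask = "MyocardialMask", source = "SourceSpec"))

setValidity("ActivationField", function(object) {
  msg <- NULL
  if (!identical(dim(object@at), dim(object@mask@mask)))
    msg <- c(msg, "at dimensions must match mask")
  a <- object@at[object@mask@mask]
  a <- a[!is.na(a)]
  if (length(a) && min(a) < object@source@originTime - 1e-9)
    msg <- c(msg, "activation times must be >= source origin time")
  if (is.null(msg)) TRUE else msg
})

#' Electromechanical delay model
#'
#' Stochastic model of the lag between local electrical depolarization and
#' the onset of mechanical shortening. Realized per-pixel delay = a Gaussian
#' draw (at segment or subject level) plus deterministic transmural-layer and
#' basal/mid/apical offsets. Defaults are the all-patients global parameters
#' (mean 45 ms, SD 28 ms); subgroup presets are provided by
#' \code{\link{emdModel}}.
#'
#' @slot globalMean numeric, mean delay in ms.
#' @slot globalSd numeric, SD of the Gaussian draw in ms.
#' @slot layerOffsets named numeric, deterministic offsets (ms) for
#'   endo/mid/epi.
#' @slot regionOffsets named numeric, deterministic offsets (ms) for
#'   basal/mid/apical.
#' @slot subgroup one of "LGE+ve", "LVSD&LGE-ve", "normal", "all".
#' @slot drawLevel "segment" (independent draw per segment/pixel) or
#'   "subject" (one draw shared by all of a subject's segments).
#' @exportClass EMDModel
setClass("EMDModel",
  representation(globalMean = "numeric", globalSd = "numeric",
    layerOffsets = "numeric", regionOffsets = "numeric",
    subgroup = "character", drawLevel = "character"),
  prototype(globalMean = 45, globalSd = 28,
    layerOffsets = c(endo = 0, mid = 0, epi = 0),
    regionOffsets = c(basal = 0, mid = 0, apical = 0),
    subgroup = "all", drawLevel = "segment"))

setValidity("EMDModel", function(object) {
  msg <- NULL
  if (object@globalSd < 0) msg <- c(msg, "globalSd must be >= 0")
  if (!all(c("endo", "mid", "epi") %in% names(object@layerOffsets)))
    msg <- c(msg, "layerOffsets must be named endo/mid/epi")
  if (!all(c("basal", "mid", "apical") %in% names(object@regionOffsets)))
    msg <- c(msg, "regionOffsets must be named basal/mid/apical")
  if (!object@drawLevel %in% c("segment", "subject"))
    msg <- c(msg, "drawLevel must be 'segment' or 'subject'")
  if (!all(is.finite(c(object@globalMean, object@globalSd,
                       object@layerOffsets, object@regionOffsets))))
    msg <- c(msg, "all EMD parameters must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Surface ECG trace
#'
#' Reference ECG recorded simultaneously with an acquisition. Carries the
#' timing-reference annotations used for multi-view co-registration: QRS
#' onset for spontaneous (VE/VT, sinus) beats, pacing-spike time for paced
#' beats. Times are ms on the acquisition clock.
#'
#' @slot samples numeric, ECG samples in mV.
#' @slot rate numeric, sampling rate in Hz.
#' @slot qrsOnset numeric, QRS onset in ms (NA if unannotated).
#' @slot pacingSpike numeric, pacing-spike time in ms (NA if none).
#' @slot beatType one of "VE", "VT", "paced", "sinus".
#' @exportClass ECGTrace
setClass("ECGTrace",
  representation(samples = "numeric", rate = "numeric", qrsOnset = "numeric",
    pacingSpike = "numeric", beatType = "character"),
  prototype(samples = numeric(), rate = 2000, qrsOnset = NA_real_,
    pacingSpike = NA_real_, beatType = "VE"))

setValidity("ECGTrace", function(object) {
  msg <- NULL
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  dur <- 1000 * length(object@samples) / object@rate
  for (ref in c(object@qrsOnset, object@pacingSpike))
    if (!is.na(ref) && (ref < 0 || ref > dur))
      msg <- c(msg, "reference annotations must lie within the trace")
  if (is.null(msg)) TRUE else msg
})

#' Incremental axial strain traces
#'
#' Per-site incremental (frame-to-frame) axial strain time series for one
#' view, with the simultaneous ECG. Sites are either all pixels of a
#' myocardial mask or an arbitrary sampled subset; the \code{sites} table
#' records, where known, raster position (row/col), mm coordinates, segment
#' label and transmural depth of each column of \code{frames}.
#'
#' @slot frames numeric matrix, frames (rows, time) x sites (columns);
#'   dimensionless signed strain.
#' @slot frameRate numeric, Hz.
#' @slot startMs numeric, acquisition-clock time of the first frame (ms).
#' @slot sites data.frame with one row per trace.
#' @slot mask the originating \linkS4class{MyocardialMask}, or NULL.
#' @slot ecg \linkS4class{ECGTrace}.
#' @exportClass StrainMovie
setClass("StrainMovie",
  representation(frames = "matrix", frameRate = "numeric", startMs = "numeric",
    sites = "data.frame", mask = "ANY", ecg = "ECGTrace"))

setValidity("StrainMovie", function(object) {
  msg <- NULL
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (ncol(object@frames) != nrow(object@sites))
    msg <- c(msg, "sites table must have one row per trace column")
  if (any(!is.finite(object@frames)))
    msg <- c(msg, "strain values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Epicardial unipolar electrogram
#'
#' A reconstructed unipolar electrogram at one epicardial node, sampled at
#' 1000 Hz. The \code{filtered} flag records whether the 100 Hz zero-phase
#' low-pass has been applied; derivative-based measurements
#' (\code{\link{computeLAT}}, \code{\link{slewRate}}) require it.
#'
#' @slot samples numeric, mV.
#' @slot rate numeric, Hz (1000 by convention).
#' @slot nodeId character.
#' @slot filtered logical.
#' @exportClass UnipolarEGM
setClass("UnipolarEGM",
  representation(samples = "numeric", rate = "numeric", nodeId = "character",
    filtered = "logical"),
  prototype(rate = 1000, nodeId = NA_character_, filtered = FALSE))

setValidity("UnipolarEGM", function(object) {
  msg <- NULL
  if (length(object@samples) < 50L)
    msg <- c(msg, "a UEGM needs at least 50 samples")
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' ECGI-style epicardial activation map
#'
#' Epicardial nodes with reconstructed unipolar electrograms and local
#' activation times (maximum negative dV/dt). Septal segments carry no
#' nodes: ECGI reconstructs the epicardial surface only.
#'
#' @slot nodes data.frame with columns node, x, y, z, segment, lat (ms).
#' @slot uegms list of \linkS4class{UnipolarEGM}, parallel to \code{nodes}.
#' @slot subject character, subject/map identifier.
#' @exportClass ECGIMap
setClass("ECGIMap",
  representation(nodes = "data.frame", uegms = "list", subject = "character"),
  prototype(subject = NA_character_))

setValidity("ECGIMap", function(object) {
  msg <- NULL
  need <- c("node", "segment", "lat")
  if (!all(need %in% names(object@nodes)))
    msg <- c(msg, "nodes needs columns node, segment, lat")
  if (length(object@uegms) != nrow(object@nodes))
    msg <- c(msg, "one UEGM per node required")
  if (is.null(msg)) TRUE else msg
})

#' Interpolated isochrone map
#'
#' Continuous electromechanical activation-time image over a myocardial
#' mask, obtained by Delaunay-based cubic interpolation of scattered
#' zero-crossing times. Pixels outside the convex hull of the samples are
#' filled with the nearest sample value and flagged extrapolated.
#'
#' @slot at numeric matrix, ms; NA outside the mask.
#' @slot extrapolated logical matrix; TRUE where hull extrapolation applied.
#' @slot mask \linkS4class{MyocardialMask}.
#' @slot method character tag.
#' @slot offset numeric, co-registration offset already subtracted (ms).
#' @exportClass IsochroneMap
setClass("IsochroneMap",
  representation(at = "matrix", extrapolated = "matrix",
    mask = "MyocardialMask", method = "character", offset = "numeric"),
  prototype(method = "delaunay-cubic", offset = 0))

setValidity("IsochroneMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@at), dim(object@mask@mask)))
    msg <- c(msg, "at dimensions must match mask")
  if (anyNA(object@at[object@mask@mask]))
    msg <- c(msg, "at must be defined on all mask pixels")
  if (is.null(msg)) TRUE else msg
})

#' Site-of-origin estimate
#'
#' Result of transmural site-of-origin localization over one or more
#' co-registered views: the 24-segment label, the transmural layer (by
#' wall-depth tercile of the earliest region's centroid), the earliest
#' activation time, and a diffuse-activation flag (diffuse maps carry layer
#' "diffuse").
#'
#' @slot segment character.
#' @slot layer one of "endo", "mid", "epi", "diffuse".
#' @slot earliestTime numeric, ms.
#' @slot diffuse logical.
#' @slot view character, view the global minimum came from.
#' @exportClass SoOEstimate
setClass("SoOEstimate",
  representation(segment = "character", layer = "character",
    earliestTime = "numeric", diffuse = "logical", view = "character"))

setValidity("SoOEstimate", function(object) {
  msg <- NULL
  if (!object@layer %in% c("endo", "mid", "epi", "diffuse"))
    msg <- c(msg, "layer must be endo/mid/epi/diffuse")
  if (object@diffuse && object@layer != "diffuse")
    msg <- c(msg, "diffuse estimates must carry layer 'diffuse'")
  if (is.null(msg)) TRUE else msg
})

#' Segmental bullseye
#'
#' One value per segment of the biventricular 24-segment model (activation
#' time or activation-time difference, ms). Uncovered segments (e.g. septal
#' segments for ECGI) are NA.
#'
#' @slot values named numeric vector of length 24, NA where masked.
#' @slot modality "EWI" or "ECGI" (or "delta").
#' @slot subject character identifier.
#' @exportClass SegmentBullseye
setClass("SegmentBullseye",
  representation(values = "numeric", modality = "character",
    subject = "character"),
  prototype(modality = "EWI", subject = NA_character_))

setValidity("SegmentBullseye", function(object) {
  msg <- NULL
  if (length(object@values) != 24L || is.null(names(object@values)))
    msg <- c(msg, "values must be a named vector of length 24")
  if (is.null(msg)) TRUE else msg
})

#' Cohort specification
#'
#' Specification of a synthetic paired EWI/ECGI cohort: number of subjects,
#' per-subject structural subgroup, and the master seed. Seeded generation is
#' reproducible bit-for-bit. The default mirrors the reference study
#' composition: 33 subjects split 20 LGE+ve, 4 LVSD&LGE-ve, 9 structurally
#' normal.
#'
#' @slot nSubjects integer.
#' @slot subgroups character vector, one of "LGE+ve", "LVSD&LGE-ve",
#'   "normal" per subject.
#' @slot seed integer master seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nSubjects = "integer", subgroups = "character",
    seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- NULL
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@subgroups) != object@nSubjects)
    msg <- c(msg, "one subgroup label per subject required")
  if (!all(object@subgroups %in% c("LGE+ve", "LVSD&LGE-ve", "normal")))
    msg <- c(msg, "unknown subgroup label")
  if (is.null(msg)) TRUE else msg
})

#' RF frame stack
#'
#' Beamformed radio-frequency frames for one view: frame x line x axial
#' sample, with the RF sampling rate, frame rate and speed of sound needed
#' to convert sample shifts to mm.
#'
#' @slot data numeric array, frame x line x sample.
#' @slot fs numeric, RF sampling rate in Hz.
#' @slot frameRate numeric, Hz.
#' @slot c numeric, speed of sound in m/s (default 1540).
#' @exportClass RFFrames
setClass("RFFrames",
  representation(data = "array", fs = "numeric", frameRate = "numeric",
    c = "numeric"),
  prototype(fs = 20e6, frameRate = 2000, c = 1540))

setValidity("RFFrames", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be frame x line x sample")
  if (dim(object@data)[1] < 2L) msg <- c(msg, "need at least 2 frames")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Interframe axial displacement field
#'
#' Axial displacement estimates between consecutive RF frames, per scan line
#' and correlation-window center, in samples and mm, with the normalized
#' correlation peak value of each estimate.
#'
#' @slot samples numeric array, framePair x line x window (displacement in
#'   RF samples; NA where the window was flat).
#' @slot mm numeric array, same shape, displacement in mm.
#' @slot corr numeric array, same shape, correlation peak in [-1, 1].
#' @slot centersMm numeric, axial window-center depths in mm.
#' @slot fs numeric, RF sampling rate (Hz).
#' @slot c numeric, speed of sound (m/s).
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(samples = "array", mm = "array", corr = "array",
    centersMm = "numeric", fs = "numeric", c = "numeric"))

#' Incremental axial strain field
#'
#' Incremental axial strain per frame pair, line and kernel center, obtained
#' as the slope of a least-squares fit of displacement versus depth.
#'
#' @slot strain numeric array, framePair x line x kernelCenter.
#' @slot centersMm numeric, kernel-center depths in mm.
#' @exportClass StrainField
setClass("StrainField",
  representation(strain = "array", centersMm = "numeric"))
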