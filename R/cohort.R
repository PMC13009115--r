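#' @include strain-synth.R ecgi-synth.R zc.R bullseye.R emd.R
NULL

#' Construct a cohort specification
#'
#' @param nSubjects number of subjects.
#' @param subgroups per-subject structural subgroup labels; default: the
#'   reference composition of 20 LGE+ve, 4 LVSD&LGE-ve and 9 structurally
#'   normal subjects, recycled/truncated to \code{nSubjects}.
#' @param seed master seed; generation is reproducible bit-for-bit.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 33, subgroups = NULL, seed = 1) {
  if (nSubjects < 1) stop("nSubjects must be >= 1")
  if (is.null(subgroups)) {
    base <- c(rep("LGE+ve", 20), rep("LVSD&LGE-ve", 4), rep("normal", 9))
    subgroups <- rep(base, length.out = nSubjects)
  }
  new("CohortSpec", nSubjects = as.integer(nSubjects),
    subgroups = subgroups, seed = as.integer(seed))
}

#' Generate a paired EWI/ECGI cohort with known ground truth
#'
#' For every subject: a focal source (random segment and transmural layer)
#' propagates over the 24-segment adjacency graph; epicardial EWI recording
#' sites receive strain traces whose downward zero crossing falls at the
#' local electrical activation time plus an electromechanical delay drawn
#' from the subject's subgroup model; ECGI nodes receive unipolar
#' electrograms whose maximum negative dV/dt falls at the electrical
#' activation time (so ECGI precedes EWI by the delay). Septal segments
#' carry no ECGI nodes. Generation is deterministic under the spec's seed.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param emd NULL (per-subject subgroup presets, \code{\link{emdModel}}) or
#'   a single \linkS4class{EMDModel} applied to every subject.
#' @param model segment model.
#' @param hopMs activation-time increment per segment hop (ms, default 20).
#' @param originTime source onset in ms after QRS onset (default 30).
#' @param sitesPerSegment epicardial EWI sites per segment (default 8).
#' @param nodesPerSegment ECGI nodes per covered segment (default 4).
#' @param jitterMs within-segment activation spread (uniform, ms).
#' @param strainNoiseSd additive strain noise SD (default 0.002, i.e. 10%
#'   of the plateau amplitude).
#' @param egmNoiseSd additive electrogram noise SD in mV (default 0.01).
#' @return list with \code{spec} and \code{subjects}, each subject a list
#'   (id, subgroup, source, segAT, ewi = \linkS4class{StrainMovie} of
#'   epicardial site traces, ecgi = \linkS4class{ECGIMap}, truth row).
#' @export
generateCohort <- function(spec, emd = NULL, model = buildSegmentModel(),
                           hopMs = 20, originTime = 30,
                           sitesPerSegment = 8, nodesPerSegment = 4,
                           jitterMs = 10, strainNoiseSd = 0.002,
                           egmNoiseSd = 0.01) {
  qrsMs <- 50; durMs <- 500; fr <- 2000
  layerSlew <- c(endo = 0.32, mid = 0.37, epi = 0.29)
  subjects <- lapply(seq_len(spec@nSubjects), function(i) {
    withr::with_seed(childSeed(spec@seed, i), {
      sg <- spec@subgroups[i]
      srcSeg <- sample(model$segment, 1)
      srcLayer <- sample(c("endo", "mid", "epi"), 1)
      segAT <- originTime + segmentDistances(model, srcSeg) * hopMs

      # per-segment electromechanical delay (shared by a segment's sites)
      m <- if (is.null(emd)) emdModel(sg) else emd
      segDelay <- realizeDelays(m, nrow(model), layer = rep("epi", nrow(model)),
        level = model$level)
      names(segDelay) <- model$segment

      siteSeg <- rep(model$segment, each = sitesPerSegment)
      siteAT <- segAT[siteSeg] + stats::runif(length(siteSeg), 0, jitterMs)
      tm <- qrsMs + siteAT + segDelay[siteSeg]
      times <- seq(0, durMs, by = 1000 / fr)
      frames <- strainTemplate(times, tm)
      if (strainNoiseSd > 0)
        frames <- frames + matrix(stats::rnorm(length(frames), 0,
          strainNoiseSd), nrow(frames), ncol(frames))
      sites <- data.frame(pixel = seq_along(siteSeg), row = NA_integer_,
        col = NA_integer_, x = NA_real_, y = NA_real_, segment = siteSeg,
        wallDepth = stats::runif(length(siteSeg), 2 / 3, 1),
        trueAt = unname(siteAT), stringsAsFactors = FALSE)
      ewi <- new("StrainMovie", frames = frames, frameRate = fr,
        startMs = 0, sites = sites, mask = NULL,
        ecg = synthesizeECG(durMs, fr, qrsMs))

      ecgi <- synthesizeECGI(segAT, model,
        nodesPerSegment = nodesPerSegment, nodeJitterMs = jitterMs,
        sourceLayer = srcLayer, slew = layerSlew[[srcLayer]],
        noiseSd = egmNoiseSd, subject = sprintf("S%02d", i))

      list(id = sprintf("S%02d", i), subgroup = sg,
        source = list(segment = srcSeg, layer = srcLayer),
        segAT = segAT, ewi = ewi, ecgi = ecgi,
        truth = data.frame(subject = sprintf("S%02d", i), segment = srcSeg,
          layer = srcLayer, subgroup = sg, stringsAsFactors = FALSE))
    })
  })
  list(spec = spec, subjects = subjects)
}

#' Per-segment electromechanical-delay table of a cohort
#'
#' Runs the measurement chain on every subject of a generated cohort:
#' zero-crossing detection on the epicardial strain traces, LAT recomputed
#' from the electrograms, bullseye extraction for both modalities, and the
#' per-segment delta (EWI_AT - ECGI_AT), stacked with subgroup labels.
#'
#' @param cohort output of \code{\link{generateCohort}}.
#' @param model segment model.
#' @return data.frame with columns subject, segment, level, chamber, delta,
#'   subgroup.
#' @export
cohortEMDTable <- function(cohort, model = buildSegmentModel()) {
  out <- lapply(cohort$subjects, function(su) {
    qrs <- su$ewi@ecg@qrsOnset
    endMs <- su$ewi@startMs +
      1000 * (nrow(su$ewi@frames) - 1) / su$ewi@frameRate
    ann <- annotateZeroCrossings(su$ewi, reference = qrs,
      window = c(qrs, endMs))
    ewiBE <- suppressWarnings(extractBullseye(
      data.frame(segment = ann$segment, at = ann$at,
        wallDepth = ann$wallDepth), model, modality = "EWI",
      subject = su$id))
    ecgiBE <- suppressWarnings(extractBullseye(su$ecgi, model,
      subject = su$id))
    d <- computeEMD(ewiBE, ecgiBE, model)
    d$subgroup <- su$subgroup
    d
  })
  do.call(rbind, out)
}
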