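#' @include cohort.R io.R score.R egm.R
NULL

#' Run the end-to-end synthetic cohort workflow
#'
#' Orchestrates the pipeline stages over a configuration:
#' \describe{
#'   \item{simulate}{generate the paired cohort; write \code{truth.csv} and
#'     the first subject's strain container.}
#'   \item{map}{zero-crossing annotation of every subject's epicardial
#'     strain traces; write \code{ewi_samples.csv}.}
#'   \item{ecgi}{electrogram measurements (LAT, morphology, slew rate) at
#'     the earliest-activating covered segment of each subject; write
#'     \code{surrogates.csv} and the layer summary \code{surrogate_summary.csv}.}
#'   \item{compare}{bullseye extraction and per-segment EWI-ECGI deltas;
#'     write \code{emd.csv} and the subgroup report \code{emd_cells.csv}.}
#'   \item{report}{segment-level localization calls (earliest bullseye
#'     segment per modality) scored against truth; write
#'     \code{localization.csv}, \code{summary.json} and a bullseye figure.}
#' }
#' A \code{manifest.json} with the seed, configuration, package version and
#' md5 of every written file is emitted last; identical configuration and
#' seed reproduce identical manifests.
#'
#' @param config list or YAML/JSON path; recognised entries: \code{seed},
#'   \code{nSubjects}, \code{subgroups}, \code{emd} (list with subgroup or
#'   mean/sd), \code{hopMs}, \code{strainNoiseSd}, \code{egmNoiseSd}.
#' @param outDir output directory (created).
#' @param stages character vector of stages to run, in pipeline order.
#' @return invisibly, a list with the in-memory stage products.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("ewirun"),
                        stages = c("simulate", "map", "ecgi", "compare",
                                   "report")) {
  cfg <- readRunConfig(config)
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  state <- list()

  if ("simulate" %in% stages) {
    emd <- if (!is.null(cfg$emd))
      emdModel(cfg$emd$subgroup %||% "all",
        globalMean = cfg$emd$mean, globalSd = cfg$emd$sd)
    else NULL
    spec <- cohortSpec(cfg$nSubjects %||% 33, cfg$subgroups, seed = seed)
    state$cohort <- generateCohort(spec, emd = emd,
      hopMs = cfg$hopMs %||% 20,
      strainNoiseSd = cfg$strainNoiseSd %||% 0.002,
      egmNoiseSd = cfg$egmNoiseSd %||% 0.01)
    put(do.call(rbind, lapply(state$cohort$subjects, `[[`, "truth")),
      "truth.csv")
    p <- file.path(outDir, "subject01_strain.h5")
    writeStrainHDF5(state$cohort$subjects[[1]]$ewi, p)
    written <- c(written, p)
  }
  needCohort <- function(stage) {
    if (is.null(state$cohort))
      stopStage(stage, "no cohort available; run the simulate stage first")
  }

  if ("map" %in% stages) {
    needCohort("map")
    state$ewiSamples <- do.call(rbind, lapply(state$cohort$subjects,
      function(su) {
        qrs <- su$ewi@ecg@qrsOnset
        endMs <- su$ewi@startMs +
          1000 * (nrow(su$ewi@frames) - 1) / su$ewi@frameRate
        ann <- annotateZeroCrossings(su$ewi, reference = qrs,
          window = c(qrs, endMs))
        cbind(subject = su$id,
          ann[, c("segment", "wallDepth", "at", "quality")])
      }))
    put(state$ewiSamples, "ewi_samples.csv")
  }

  if ("ecgi" %in% stages) {
    needCohort("ecgi")
    state$surrogates <- do.call(rbind, lapply(state$cohort$subjects,
      function(su) {
        nodes <- su$ecgi@nodes
        soSeg <- nodes$segment[which.min(nodes$lat)]
        k <- which(nodes$segment == soSeg)
        data.frame(subject = su$id, layer = su$source$layer,
          slew = mean(vapply(su$ecgi@uegms[k], slewRate, numeric(1))),
          morphology = names(which.max(table(vapply(su$ecgi@uegms[k],
            classifyMorphology, character(1))))),
          stringsAsFactors = FALSE)
      }))
    put(state$surrogates, "surrogates.csv")
    if (length(unique(state$surrogates$layer)) >= 2) {
      ss <- surrogateStats(state$surrogates)
      put(cbind(ss$table, anovaP = ss$anovaP, chisqP = ss$chisqP),
        "surrogate_summary.csv")
    }
  }

  if ("compare" %in% stages) {
    needCohort("compare")
    state$emd <- cohortEMDTable(state$cohort)
    put(state$emd, "emd.csv")
    if (length(unique(state$emd$subgroup)) >= 2) {
      sa <- subgroupAnalysis(state$emd)
      put(cbind(sa$cells, anovaP = sa$anovaP[sa$cells$row]), "emd_cells.csv")
    }
  }

  if ("report" %in% stages) {
    needCohort("report")
    model <- buildSegmentModel()
    calls <- do.call(rbind, lapply(state$cohort$subjects, function(su) {
      qrs <- su$ewi@ecg@qrsOnset
      endMs <- su$ewi@startMs +
        1000 * (nrow(su$ewi@frames) - 1) / su$ewi@frameRate
      ann <- annotateZeroCrossings(su$ewi, reference = qrs,
        window = c(qrs, endMs))
      ewiBE <- suppressWarnings(extractBullseye(
        data.frame(segment = ann$segment, at = ann$at,
          wallDepth = ann$wallDepth), model, subject = su$id))
      ecgiBE <- suppressWarnings(extractBullseye(su$ecgi, model,
        subject = su$id))
      data.frame(map = su$id,
        ewiSegment = names(which.min(ewiBE@values)),
        ewiLayer = NA_character_, ewiDiffuse = FALSE,
        ecgiSegment = names(which.min(ecgiBE@values)),
        stringsAsFactors = FALSE)
    }))
    truth <- do.call(rbind, lapply(state$cohort$subjects, function(su)
      data.frame(map = su$id, segment = su$source$segment,
        layer = su$source$layer, stringsAsFactors = FALSE)))
    sc <- scoreLocalization(calls, truth, model)
    state$localization <- sc
    put(sc, "localization.csv")
    agg <- aggregateLocalization(sc)
    p <- file.path(outDir, "summary.json")
    jsonlite::write_json(list(
      ewiSegmentPct = agg$ewiSegment$pct, ecgiSegmentPct = agg$ecgiSegment$pct,
      agreementPct = agg$agreementCorrect$pct,
      bothFailedPct = agg$bothFailed$pct, nMaps = agg$nMaps),
      p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
    fig <- file.path(outDir, "bullseye_subject01.png")
    grDevices::png(fig, width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    be <- suppressWarnings(extractBullseye(state$cohort$subjects[[1]]$ecgi,
      model))
    plotBullseye(be, main = "ECGI activation, subject 01")
  }

  manifest <- list(package = as.character(utils::packageVersion("ewimap")),
    rversion = R.version.string, seed = seed, config = cfg,
    files = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(c(state, list(outDir = outDir, manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
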