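#' @include activation.R
NULL

#' Electromechanical delay model constructor and subgroup presets
#'
#' Parameters are the per-subgroup global electromechanical-delay statistics
#' of the reference cohort: all patients 45 +/- 28 ms; LGE+ve 50 +/- 29 ms;
#' LVSD & LGE-ve 39 +/- 25 ms; structurally normal 33 +/- 21 ms.
#'
#' @param subgroup "all", "LGE+ve", "LVSD&LGE-ve" or "normal"; selects the
#'   preset mean/SD unless overridden.
#' @param globalMean,globalSd override the preset Gaussian parameters (ms).
#' @param layerOffsets,regionOffsets deterministic offsets (ms), named
#'   endo/mid/epi and basal/mid/apical.
#' @param drawLevel "segment" (independent Gaussian draw per segment) or
#'   "subject" (one draw per subject shared across segments).
#' @return an \linkS4class{EMDModel}.
#' @examples
#' emdModel("all")
#' emdModel("LGE+ve")
#' @export
emdModel <- function(subgroup = "all", globalMean = NULL, globalSd = NULL,
                     layerOffsets = c(endo = 0, mid = 0, epi = 0),
                     regionOffsets = c(basal = 0, mid = 0, apical = 0),
                     drawLevel = "segment") {
  presets <- list("all" = c(45, 28), "LGE+ve" = c(50, 29),
    "LVSD&LGE-ve" = c(39, 25), "normal" = c(33, 21))
  if (!subgroup %in% names(presets)) stop("unknown subgroup '", subgroup, "'")
  p <- presets[[subgroup]]
  new("EMDModel",
    globalMean = if (is.null(globalMean)) p[1] else globalMean,
    globalSd = if (is.null(globalSd)) p[2] else globalSd,
    layerOffsets = layerOffsets, regionOffsets = regionOffsets,
    subgroup = subgroup, drawLevel = drawLevel)
}

#' Realize electromechanical delays
#'
#' Draws delays under an \linkS4class{EMDModel}: one Gaussian draw per entry
#' ("segment" level) or a single shared draw ("subject" level), plus the
#' deterministic layer and basal/mid/apical offsets. Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @param emd an \linkS4class{EMDModel}.
#' @param n number of delays.
#' @param layer optional character vector ("endo"/"mid"/"epi") per entry.
#' @param level optional character vector ("basal"/"mid"/"apical") per entry.
#' @return numeric vector of delays in ms.
#' @export
realizeDelays <- function(emd, n, layer = NULL, level = NULL) {
  draw <- if (emd@drawLevel == "subject")
    rep(stats::rnorm(1, emd@globalMean, emd@globalSd), n)
  else stats::rnorm(n, emd@globalMean, emd@globalSd)
  if (!is.null(layer)) draw <- draw + emd@layerOffsets[layer]
  if (!is.null(level)) draw <- draw + emd@regionOffsets[level]
  unname(draw)
}

# smooth strain template: positive diastolic plateau, downward zero crossing
# at exactly tm, negative systolic plateau, linear recovery back to positive.
# times: vector (ms); tm: vector per site (ms). Returns length(times) x
# length(tm) matrix.
strainTemplate <- function(times, tm, amplitude = 0.02, widthMs = 4,
                           systolicMs = 150, recoverMs = 100) {
  nf <- length(times); np <- length(tm)
  tt <- matrix(times, nf, np)
  tmm <- matrix(tm, nf, np, byrow = TRUE)
  s <- amplitude * tanh((tmm - tt) / widthMs)
  rec <- tt > tmm + systolicMs
  s[rec] <- pmin(amplitude,
    -amplitude + 2 * amplitude * ((tt - tmm - systolicMs)[rec]) / recoverMs)
  s
}

#' Synthesize a reference ECG trace
#'
#' Minimal surface-ECG emulation carrying the timing annotations the
#' pipeline co-registers on: an R-wave (Gaussian bump) at \code{qrsOnset}
#' plus, for paced beats, a narrow pacing spike.
#'
#' @param durationMs trace duration in ms.
#' @param rate sampling rate in Hz.
#' @param qrsOnset QRS onset in ms.
#' @param beatType "VE", "VT", "paced" or "sinus".
#' @param pacingSpike pacing-spike time in ms (paced beats).
#' @return an \linkS4class{ECGTrace}.
#' @export
synthesizeECG <- function(durationMs = 450, rate = 2000, qrsOnset = 50,
                          beatType = "VE", pacingSpike = NA_real_) {
  t <- seq(0, durationMs, by = 1000 / rate)
  s <- 1.2 * exp(-((t - qrsOnset - 25)^2) / (2 * 8^2))  # R wave after onset
  if (!is.na(pacingSpike))
    s <- s + 2 * exp(-((t - pacingSpike)^2) / (2 * 0.8^2))
  new("ECGTrace", samples = s, rate = rate, qrsOnset = qrsOnset,
    pacingSpike = pacingSpike, beatType = beatType)
}

#' Synthesize an incremental axial strain movie
#'
#' Builds per-pixel strain traces over an activation field: each trace is
#' positive (diastolic) before the local mechanical activation time
#' t_m = electrical AT + electromechanical delay, crosses zero downward at
#' t_m (within half a frame period once sampled), stays negative for the
#' systolic duration, then recovers. Additive Gaussian noise and an optional
#' slow baseline drift are applied after construction. The electrical AT is
#' relative to QRS onset; the movie clock starts at \code{startMs} and the
#' ECG's QRS onset sits at \code{qrsOnsetMs}, so the crossing occurs at
#' qrsOnsetMs + AT + delay on the movie clock.
#'
#' @param field an \linkS4class{ActivationField}.
#' @param delay electromechanical delay: a scalar, a per-site vector, or an
#'   \linkS4class{EMDModel} (realized per site with the current RNG).
#' @param pixels optional linear indices of mask pixels to synthesize
#'   (default: all mask pixels).
#' @param durationMs movie duration in ms (default 450).
#' @param qrsOnsetMs QRS onset on the movie clock (default 50 ms).
#' @param amplitude plateau strain amplitude (default 0.02).
#' @param widthMs transition half-width of the crossing in ms.
#' @param systolicMs duration the trace stays negative (default 150 ms).
#' @param noiseSd additive Gaussian noise SD (strain units).
#' @param driftAmp amplitude of an optional sinusoidal baseline drift.
#' @param beatType,pacingSpike passed to \code{\link{synthesizeECG}}.
#' @return a \linkS4class{StrainMovie}.
#' @examples
#' m <- buildStripMask(20, 5, spacing = 1)
#' f <- simulateActivation(m, sourceSpec("S1", cv = 1), sourcePixel = c(3, 1))
#' mov <- synthesizeStrain(f, delay = 0, durationMs = 200)
#' @export
synthesizeStrain <- function(field, delay = 0, pixels = NULL,
                             durationMs = 450, qrsOnsetMs = 50,
                             amplitude = 0.02, widthMs = 4, systolicMs = 150,
                             noiseSd = 0, driftAmp = 0,
                             beatType = "VE", pacingSpike = NA_real_) {
  mask <- field@mask
  fr <- if (!is.null(mask@geometry)) mask@geometry@frameRate else 2000
  if (is.null(pixels)) pixels <- which(mask@mask)
  at <- field@at[pixels]
  if (anyNA(at)) stop("activation undefined at requested pixels")
  co <- maskCoords(mask, pixels)
  wd <- mask@wallDepth[pixels]
  segIdx <- mask@segmentIdx[pixels]
  seg <- ifelse(segIdx > 0, mask@segmentLabels[pmax(segIdx, 1L)],
    "unassigned")

  if (is(delay, "EMDModel"))
    delay <- realizeDelays(delay, length(pixels), layer = layerOfDepth(wd))
  tm <- qrsOnsetMs + at + delay
  times <- seq(0, durationMs, by = 1000 / fr)
  if (any(tm <= times[1] + widthMs) || any(tm >= times[length(times)]))
    stop("mechanical activation time outside the movie duration")

  s <- strainTemplate(times, tm, amplitude, widthMs, systolicMs)
  if (noiseSd > 0) s <- s + matrix(stats::rnorm(length(s), 0, noiseSd),
    nrow(s), ncol(s))
  if (driftAmp > 0) {
    ph <- stats::runif(ncol(s), 0, 2 * pi)
    s <- s + driftAmp * sin(outer(times / durationMs * 2 * pi, rep(1, ncol(s)))
      + matrix(ph, nrow(s), ncol(s), byrow = TRUE))
  }
  sites <- data.frame(pixel = pixels, row = co$row, col = co$col,
    x = co$x, y = co$y, segment = seg, wallDepth = wd,
    trueAt = at, stringsAsFactors = FALSE)
  ecg <- synthesizeECG(durationMs, fr, qrsOnsetMs, beatType, pacingSpike)
  new("StrainMovie", frames = s, frameRate = fr, startMs = 0,
    sites = sites, mask = mask, ecg = ecg)
}
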