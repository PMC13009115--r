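#' @include egm.R segments.R
NULL

# canonical UEGM waveform: QS-type sigmoid fall with steepest descent at
# `atMs`, optional initial r bump peaking `rLeadMs` before; mV at `rate` Hz.
uegmWaveform <- function(atMs, durationMs = 450, rate = 1000, slew = 0.32,
                         widthMs = 8, rAmpMv = 0, rLeadMs = 20,
                         rSigmaMs = 5, noiseSd = 0) {
  t <- seq(0, durationMs, by = 1000 / rate)
  amp <- 2 * slew * widthMs
  v <- -(amp / 2) * (1 + tanh((t - atMs) / widthMs))
  if (rAmpMv > 0)
    v <- v + rAmpMv * exp(-((t - (atMs - rLeadMs))^2) / (2 * rSigmaMs^2))
  if (noiseSd > 0) v <- v + stats::rnorm(length(t), 0, noiseSd)
  v
}

#' Synthesize an ECGI-style epicardial activation map
#'
#' Builds reconstructed unipolar electrograms on epicardial nodes so that
#' each node's maximum negative dV/dt falls at its electrical activation
#' time (1000 Hz sampling, 100 Hz zero-phase low-pass applied before LAT
#' detection). Morphology follows the configured source layer: QS (no
#' initial r deflection) for epicardial sources, rS otherwise; the r
#' amplitude and the slew rate at the crossing are configurable. Septal
#' segments carry no nodes and requesting them is an error.
#'
#' @param segmentAT named numeric vector of electrical activation times
#'   (ms, QRS-relative) per segment, or an \linkS4class{ActivationField}
#'   (its epicardial restriction, mean AT of wall depth >= 2/3 per segment,
#'   is used).
#' @param model segment model from \code{\link{buildSegmentModel}}.
#' @param segments segments to populate; default: all ECGI-covered segments
#'   with an AT.
#' @param nodesPerSegment nodes per covered segment (default 4).
#' @param nodeJitterMs half-width of uniform within-segment AT spread (ms).
#' @param sourceLayer "endo", "mid" or "epi"; "epi" yields QS morphology,
#'   otherwise rS.
#' @param slew configured slew rate at the intrinsic deflection (mV/ms).
#' @param rFraction r-wave amplitude as a fraction of the S amplitude
#'   (rS morphology only; default 0.25).
#' @param durationMs,rate trace duration (ms) and sampling rate (Hz).
#' @param noiseSd additive Gaussian noise SD (mV) before filtering.
#' @param subject subject/map identifier.
#' @return an \linkS4class{ECGIMap}; node LATs are computed from the built
#'   electrograms with \code{\link{computeLAT}}.
#' @export
synthesizeECGI <- function(segmentAT, model = buildSegmentModel(),
                           segments = NULL, nodesPerSegment = 4,
                           nodeJitterMs = 0, sourceLayer = "endo",
                           slew = 0.32, rFraction = 0.25,
                           durationMs = 450, rate = 1000, noiseSd = 0,
                           subject = NA_character_) {
  if (is(segmentAT, "ActivationField")) {
    msk <- segmentAT@mask
    px <- which(msk@mask & msk@wallDepth >= 2 / 3 & msk@segmentIdx > 0)
    segmentAT <- tapply(segmentAT@at[px],
      msk@segmentLabels[msk@segmentIdx[px]], mean, na.rm = TRUE)
    segmentAT <- stats::setNames(as.numeric(segmentAT), names(segmentAT))
  }
  covered <- model$segment[model$ecgiCovered]
  if (is.null(segments)) segments <- intersect(names(segmentAT), covered)
  bad <- setdiff(segments, covered)
  if (length(bad))
    stop("ECGI does not cover septal segments: ", paste(bad, collapse = ", "))
  miss <- setdiff(segments, names(segmentAT))
  if (length(miss)) stop("no activation time for: ", paste(miss, collapse = ", "))

  rAmp <- if (sourceLayer == "epi") 0 else rFraction * 2 * slew * 8
  nodes <- NULL; uegms <- list()
  levNum <- c(basal = 0, mid = 1, apical = 2)
  for (s in segments) {
    row <- model[model$segment == s, ]
    secIdx <- match(s, model$segment)
    for (k in seq_len(nodesPerSegment)) {
      at <- segmentAT[[s]] +
        if (nodeJitterMs > 0) stats::runif(1, 0, nodeJitterMs) else 0
      id <- sprintf("%s.n%02d", s, k)
      u <- unipolarEGM(uegmWaveform(at, durationMs, rate, slew,
        rAmpMv = rAmp, noiseSd = noiseSd), rate, id)
      u <- lowpassUEGM(u)
      th <- 2 * pi * (secIdx + k / (nodesPerSegment + 1)) / 24
      nodes <- rbind(nodes, data.frame(node = id,
        x = 40 * cos(th), y = 40 * sin(th),
        z = 30 * levNum[[row$level]] + 3 * k,
        segment = s, lat = computeLAT(u), stringsAsFactors = FALSE))
      uegms[[id]] <- u
    }
  }
  rownames(nodes) <- NULL
  new("ECGIMap", nodes = nodes, uegms = unname(uegms), subject = subject)
}
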