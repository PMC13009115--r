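#' @include AllClasses.R utils.R
NULL

#' Construct a unipolar electrogram
#'
#' @param samples numeric, mV.
#' @param rate sampling rate in Hz (default 1000).
#' @param nodeId node identifier.
#' @param filtered whether the 100 Hz low-pass has been applied.
#' @return a \linkS4class{UnipolarEGM}.
#' @export
unipolarEGM <- function(samples, rate = 1000, nodeId = NA_character_,
                        filtered = FALSE) {
  new("UnipolarEGM", samples = as.numeric(samples), rate = rate,
    nodeId = nodeId, filtered = filtered)
}

#' Zero-phase 100 Hz low-pass of a unipolar electrogram
#'
#' 4th-order Butterworth applied forward-backward (zero phase) with a
#' 100 Hz corner, the conditioning applied to reconstructed electrograms
#' before any derivative-based measurement.
#'
#' @param uegm a \linkS4class{UnipolarEGM}.
#' @param cutoffHz corner frequency (default 100).
#' @return the filtered \linkS4class{UnipolarEGM} (\code{filtered = TRUE}).
#' @export
lowpassUEGM <- function(uegm, cutoffHz = 100) {
  bf <- signal::butter(4, cutoffHz / (uegm@rate / 2), type = "low")
  out <- as.numeric(signal::filtfilt(bf, uegm@samples))
  unipolarEGM(out, uegm@rate, uegm@nodeId, filtered = TRUE)
}

# central first difference in mV/ms; end samples get NA
centralDiff <- function(x, rate) {
  n <- length(x)
  d <- rep(NA_real_, n)
  dtMs <- 1000 / rate
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dtMs)
  d
}

#' Local activation time by maximum negative dV/dt
#'
#' LAT is the sample time of the minimum central first difference of the
#' (100 Hz low-passed) unipolar electrogram, in ms from the start of the
#' trace; ties break to the earliest sample. A signal with no negative
#' slope anywhere (monotone non-decreasing) has no defined LAT and returns
#' NA with a warning.
#'
#' @param uegm a \linkS4class{UnipolarEGM} with \code{filtered = TRUE}.
#' @return LAT in ms, or NA if undefined.
#' @export
computeLAT <- function(uegm) {
  if (!uegm@filtered)
    stop("computeLAT requires the 100 Hz low-passed electrogram; ",
      "apply lowpassUEGM() first")
  d <- centralDiff(uegm@samples, uegm@rate)
  ok <- which(!is.na(d))
  if (!length(ok) || min(d[ok]) >= 0) {
    warning("no negative slope: LAT undefined")
    return(NA_real_)
  }
  i <- ok[which.min(d[ok])]  # which.min takes the earliest tie
  (i - 1) * 1000 / uegm@rate
}

#' Slew rate of a unipolar electrogram
#'
#' Magnitude of the steepest negative slope: |min central first difference|
#' in mV/ms, 0 for traces without negative slope.
#'
#' @param uegm a \linkS4class{UnipolarEGM} with \code{filtered = TRUE}.
#' @return slew rate in mV/ms (>= 0).
#' @export
slewRate <- function(uegm) {
  if (!uegm@filtered)
    stop("slewRate requires the 100 Hz low-passed electrogram")
  if (length(uegm@samples) < 3L) stop("slew rate undefined on < 3 samples")
  d <- centralDiff(uegm@samples, uegm@rate)
  max(0, -min(d, na.rm = TRUE))
}

#' QS / rS morphology classification
#'
#' A unipolar electrogram is rS when an initial positive (r) deflection
#' above \code{rThreshold} times the dominant negative amplitude precedes
#' the dominant negative (S) deflection, QS when the dominant negative
#' deflection has no such initial positivity, and "other" when there is no
#' dominant negative deflection at all. Amplitudes are measured against the
#' mean of the first \code{baselineMs} ms.
#'
#' @param uegm a \linkS4class{UnipolarEGM}.
#' @param rThreshold r-wave threshold as a fraction of |global minimum|
#'   (default 0.1).
#' @param baselineMs baseline window length in ms (default 10).
#' @return "QS", "rS" or "other".
#' @export
classifyMorphology <- function(uegm, rThreshold = 0.1, baselineMs = 10) {
  x <- uegm@samples
  nb <- max(2L, round(baselineMs / 1000 * uegm@rate))
  x <- x - mean(x[seq_len(min(nb, length(x)))])
  if (all(abs(x) < 1e-12)) {
    warning("flat (all-zero) electrogram")
    return("other")
  }
  gmin <- min(x)
  if (gmin >= -1e-9) return("other")      # no dominant negative deflection
  imin <- which.min(x)
  rAmp <- max(0, max(x[seq_len(imin)]))
  if (rAmp > rThreshold * abs(gmin)) "rS" else "QS"
}

#' Correlation-gated temporal beat averaging
#'
#' Aligns candidate beats to a template at the lag of maximum
#' cross-correlation, keeps beats whose Pearson correlation with the
#' template at that lag reaches the threshold (0.93 by convention), and
#' averages the accepted beats pointwise on the template's support.
#'
#' @param beats numeric matrix (beats x samples) or list of equal-length
#'   numeric vectors.
#' @param template numeric vector, the cluster template.
#' @param threshold correlation acceptance threshold (default 0.93).
#' @param maxLag alignment search range in samples (default 30).
#' @return list with \code{average} (numeric), \code{accepted} (logical per
#'   beat), \code{n} accepted count, \code{correlations}.
#' @export
averageBeats <- function(beats, template, threshold = 0.93, maxLag = 30) {
  if (is.list(beats)) beats <- do.call(rbind, beats)
  L <- length(template)
  if (L > ncol(beats)) stop("template longer than the beats")
  nb <- nrow(beats)
  lags <- -maxLag:maxLag
  bestLag <- integer(nb); bestCor <- numeric(nb)
  for (b in seq_len(nb)) {
    cors <- vapply(lags, function(l) {
      i1 <- max(1, 1 + l); i2 <- min(ncol(beats), L + l)
      if (i2 - i1 < 10) return(-Inf)
      seg <- beats[b, i1:i2]
      tem <- template[(i1 - l):(i2 - l)]
      if (stats::sd(seg) == 0 || stats::sd(tem) == 0) return(-Inf)
      stats::cor(seg, tem)
    }, numeric(1))
    k <- which.max(cors)
    bestLag[b] <- lags[k]; bestCor[b] <- cors[k]
  }
  accepted <- bestCor >= threshold
  if (!any(accepted)) stop("zero beats accepted at threshold ", threshold)
  aligned <- matrix(NA_real_, sum(accepted), L)
  for (k in seq_len(sum(accepted))) {
    b <- which(accepted)[k]
    src <- seq_len(L) + bestLag[b]
    ok <- src >= 1 & src <= ncol(beats)
    aligned[k, ok] <- beats[b, src[ok]]
  }
  list(average = colMeans(aligned, na.rm = TRUE), accepted = accepted,
    n = sum(accepted), correlations = bestCor)
}

#' Axial-surrogate statistics across transmural layers
#'
#' Per-layer slew-rate mean +/- SD and QS-morphology fraction, a one-way
#' ANOVA of slew rate across layers, and a chi-square contingency test of
#' morphology versus layer — the surrogate table used to judge whether
#' reconstructed epicardial electrograms separate endo-, mid- and
#' epicardial sites of origin.
#'
#' @param records data.frame with columns \code{layer} ("endo"/"mid"/"epi"),
#'   \code{slew} (mV/ms, >= 0) and \code{morphology} ("QS"/"rS"/"other").
#' @return list with \code{table} (per-layer summary), \code{anovaP},
#'   \code{chisqP}.
#' @export
surrogateStats <- function(records) {
  stopifnot(all(c("layer", "slew", "morphology") %in% names(records)))
  if (any(records$slew < 0)) stop("slew rates must be >= 0")
  cnt <- table(records$layer)
  if (length(cnt) < 2L) stop("at least 2 layers must be represented")
  small <- names(cnt)[cnt < 2]
  keep <- !(records$layer %in% small)
  if (length(small))
    warning("layer(s) with < 2 records excluded from ANOVA: ",
      paste(small, collapse = ", "))
  layers <- intersect(c("endo", "mid", "epi"), unique(records$layer))
  tab <- do.call(rbind, lapply(layers, function(l) {
    r <- records[records$layer == l, ]
    data.frame(layer = l, n = nrow(r), slewMean = mean(r$slew),
      slewSd = stats::sd(r$slew),
      qsFraction = mean(r$morphology == "QS"))
  }))
  anovaP <- if (length(unique(records$layer[keep])) >= 2)
    summary(stats::aov(slew ~ factor(layer),
      data = records[keep, ]))[[1]][["Pr(>F)"]][1]
  else NA_real_
  chisqP <- tryCatch(suppressWarnings(
    stats::chisq.test(table(records$layer, records$morphology))$p.value),
    error = function(e) NA_real_)
  list(table = tab, anovaP = anovaP, chisqP = chisqP)
}
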