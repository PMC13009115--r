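#' @include AllClasses.R
NULL

#' Synthesize beamformed RF frames under a displacement schedule
#'
#' Each scan line is a random scatterer train convolved with a
#' Gaussian-modulated pulse (center frequency 2.5 MHz by default). Frame k
#' displaces every scatterer axially by the cumulative displacement the
#' schedule prescribes at its depth, so consecutive frames differ by the
#' interframe displacement the estimator should recover. Axial sample
#' spacing is c / (2 fs).
#'
#' @param displacementMm either a function(depthMm, frameIndex) returning
#'   the cumulative axial displacement in mm, or a single number applied to
#'   all depths at every frame after the first.
#' @param nFrames number of frames (>= 2).
#' @param nLines number of scan lines.
#' @param depthMm imaging depth in mm.
#' @param fs RF sampling rate in Hz (>= 4 x pulse center frequency).
#' @param frameRate frame rate in Hz.
#' @param fc pulse center frequency in Hz (default 2.5 MHz).
#' @param bandwidth fractional bandwidth of the Gaussian pulse (default 0.6).
#' @param scatterersPerMm scatterer density per mm (default 8).
#' @param c speed of sound in m/s (default 1540).
#' @param noiseSd additive white noise SD relative to unit scatterer
#'   amplitude.
#' @param seed integer seed for the scatterer train and noise.
#' @return an \linkS4class{RFFrames}.
#' @export
synthesizeRF <- function(displacementMm, nFrames = 2, nLines = 4,
                         depthMm = 30, fs = 20e6, frameRate = 2000,
                         fc = 2.5e6, bandwidth = 0.6, scatterersPerMm = 8,
                         c = 1540, noiseSd = 0, seed = 1) {
  if (fs < 4 * fc) stop("fs must be at least 4x the pulse center frequency")
  dz <- c / (2 * fs) * 1000                 # axial sample spacing, mm
  ns <- ceiling(depthMm / dz)
  zSamp <- (seq_len(ns) - 1) * dz
  dispFun <- if (is.function(displacementMm)) displacementMm
    else function(z, k) rep(if (k > 1) displacementMm else 0, length(z))
  sigmaT <- 1 / (bandwidth * fc * pi) # Gaussian envelope width, s
  halfW <- ceiling(3 * sigmaT * fs)

  out <- array(0, dim = c(nFrames, nLines, ns))
  withr::with_seed(seed, {
    for (l in seq_len(nLines)) {
      nSc <- round(depthMm * scatterersPerMm)
      z0 <- stats::runif(nSc, 0, depthMm)
      a <- stats::rnorm(nSc)
      for (k in seq_len(nFrames)) {
        z <- z0 + dispFun(z0, k)
        tauSamp <- z / dz                    # arrival in sample units
        line <- numeric(ns)
        for (j in seq_len(nSc)) {
          i0 <- max(1, floor(tauSamp[j]) - halfW)
          i1 <- min(ns, ceiling(tauSamp[j]) + halfW)
          if (i1 < i0) next
          dt <- ((i0:i1) - 1 - tauSamp[j]) / fs
          line[i0:i1] <- line[i0:i1] +
            a[j] * exp(-dt^2 / (2 * sigmaT^2)) * cos(2 * pi * fc * dt)
        }
        out[k, l, ] <- line
      }
    }
    if (noiseSd > 0)
      out <- out + array(stats::rnorm(length(out), 0, noiseSd), dim(out))
  })
  new("RFFrames", data = out, fs = fs, frameRate = frameRate, c = c)
}
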