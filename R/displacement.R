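#' @include rf-synth.R mask.R
NULL

# normalized cross-correlation of window x against y at integer lags
# -search..search, with parabolic sub-sample refinement around the peak.
# Returns c(displacement in samples, peak correlation) or NA if flat.
nccEstimate <- function(x, yFull, start, len, search) {
  xw <- x[start:(start + len - 1)]
  if (stats::sd(xw) == 0) return(c(NA_real_, NA_real_))
  lags <- -search:search
  cors <- vapply(lags, function(l) {
    i0 <- start + l
    if (i0 < 1 || i0 + len - 1 > length(yFull)) return(NA_real_)
    yw <- yFull[i0:(i0 + len - 1)]
    if (stats::sd(yw) == 0) return(NA_real_)
    stats::cor(xw, yw)
  }, numeric(1))
  if (all(is.na(cors))) return(c(NA_real_, NA_real_))
  k <- which.max(cors)
  d <- lags[k]
  # parabolic interpolation of the correlation peak (skipped for an exact
  # integer match, where the peak is already 1)
  if (cors[k] < 1 - 1e-12 &&
      k > 1 && k < length(cors) && !is.na(cors[k - 1]) && !is.na(cors[k + 1])) {
    den <- cors[k - 1] - 2 * cors[k] + cors[k + 1]
    if (is.finite(den) && den < 0)
      d <- d + 0.5 * (cors[k - 1] - cors[k + 1]) / den
  }
  c(d, cors[k])
}

#' Estimate interframe axial displacement from RF frames
#'
#' 1-D normalized cross-correlation between consecutive frames per scan
#' line: overlapping axial windows are matched over an integer lag search
#' range and the correlation peak is refined by parabolic sub-sample
#' interpolation. Flat (zero-variance) windows yield NA with the flag
#' preserved in the correlation array.
#'
#' @param frames an \linkS4class{RFFrames}.
#' @param windowLen correlation window length in samples (>= 8).
#' @param overlap window overlap fraction in [0, 1) (default 0.8).
#' @param search integer search range in samples (default 8).
#' @return a \linkS4class{DisplacementField}.
#' @export
estimateDisplacement <- function(frames, windowLen = 64, overlap = 0.8,
                                 search = 8) {
  if (windowLen < 8) stop("window length must be >= 8 samples")
  if (search < 1) stop("search range must be >= 1 sample")
  d <- dim(frames@data)
  nF <- d[1]; nL <- d[2]; nS <- d[3]
  step <- max(1L, round(windowLen * (1 - overlap)))
  starts <- seq(1L + search, nS - windowLen + 1L - search, by = step)
  if (!length(starts)) stop("frames too short for the window and search")
  dzMm <- frames@c / (2 * frames@fs) * 1000
  centers <- (starts + (windowLen - 1) / 2 - 1) * dzMm

  disp <- array(NA_real_, c(nF - 1, nL, length(starts)))
  corr <- array(NA_real_, c(nF - 1, nL, length(starts)))
  for (k in seq_len(nF - 1)) for (l in seq_len(nL)) {
    x <- frames@data[k, l, ]
    y <- frames@data[k + 1, l, ]
    for (w in seq_along(starts)) {
      est <- nccEstimate(x, y, starts[w], windowLen, search)
      disp[k, l, w] <- est[1]
      corr[k, l, w] <- est[2]
    }
  }
  new("DisplacementField", samples = disp, mm = disp * dzMm, corr = corr,
    centersMm = centers, fs = frames@fs, c = frames@c)
}

#' Incremental axial strain by least-squares gradient
#'
#' Incremental (frame-to-frame) axial strain at each kernel center is the
#' slope of the least-squares line fit of axial displacement versus depth
#' over the kernel — exact for displacement profiles linear in depth.
#'
#' @param disp a \linkS4class{DisplacementField}.
#' @param kernelMm strain-estimation kernel length in mm (default 5); must
#'   span at least 2 displacement estimates.
#' @return a \linkS4class{StrainField}.
#' @export
estimateIncrementalStrain <- function(disp, kernelMm = 5) {
  z <- disp@centersMm
  nW <- length(z)
  half <- kernelMm / 2
  members <- lapply(seq_len(nW), function(w)
    which(abs(z - z[w]) <= half + 1e-9))
  if (any(vapply(members, length, integer(1)) < 2))
    stop("kernel shorter than 2 displacement-estimate spacings")
  d <- dim(disp@mm)
  strain <- array(NA_real_, c(d[1], d[2], nW))
  for (k in seq_len(d[1])) for (l in seq_len(d[2])) {
    u <- disp@mm[k, l, ]
    for (w in seq_len(nW)) {
      m <- members[[w]]
      um <- u[m]; zm <- z[m]
      ok <- !is.na(um)
      if (sum(ok) < 2) next
      zc <- zm[ok] - mean(zm[ok])
      strain[k, l, w] <- sum(zc * um[ok]) / sum(zc^2)
    }
  }
  new("StrainField", strain = strain, centersMm = z)
}

#' Resample an estimated strain field onto mask pixels
#'
#' Nearest-estimate assignment of kernel-center strain traces to the pixels
#' of a myocardial mask (estimates live on the scan-line/depth grid; the
#' mask on the Cartesian raster). Pixels farther than \code{maxDistMm} from
#' any estimate are rejected; an empty overlap is an error.
#'
#' @param strain a \linkS4class{StrainField}.
#' @param mask a \linkS4class{MyocardialMask}.
#' @param lineX x-positions (mm) of the scan lines, one per line of the
#'   strain array.
#' @param frameRate frame rate in Hz for the resulting movie.
#' @param maxDistMm maximum pixel-to-estimate distance (default 2 mm).
#' @return a \linkS4class{StrainMovie} whose frames are the per-pixel
#'   incremental strain traces.
#' @export
strainToTraces <- function(strain, mask, lineX, frameRate = 2000,
                           maxDistMm = 2) {
  d <- dim(strain@strain)
  stopifnot(length(lineX) == d[2])
  grid <- expand.grid(line = seq_len(d[2]), w = seq_len(d[3]))
  gx <- lineX[grid$line]
  gy <- strain@centersMm[grid$w]
  idx <- which(mask@mask)
  co <- maskCoords(mask, idx)
  near <- integer(length(idx)); dist2 <- numeric(length(idx))
  for (i in seq_along(idx)) {
    dd <- (gx - co$x[i])^2 + (gy - co$y[i])^2
    near[i] <- which.min(dd)
    dist2[i] <- dd[near[i]]
  }
  ok <- dist2 <= maxDistMm^2
  if (!any(ok)) stop("empty overlap between estimator grid and mask")
  frames <- matrix(NA_real_, d[1], sum(ok))
  for (j in seq_len(sum(ok))) {
    g <- grid[near[ok][j], ]
    frames[, j] <- strain@strain[, g$line, g$w]
  }
  frames[!is.finite(frames)] <- 0
  sites <- cbind(data.frame(pixel = idx[ok]), co[ok, c("row", "col", "x", "y")])
  sites$segment <- "unassigned"; sites$wallDepth <- mask@wallDepth[idx[ok]]
  new("StrainMovie", frames = frames, frameRate = frameRate, startMs = 0,
    sites = sites, mask = mask,
    ecg = synthesizeECG(1000 * (d[1] - 1) / frameRate, frameRate,
      qrsOnset = 0))
}
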