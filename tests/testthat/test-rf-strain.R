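dzMm <- axialSampleSpacing()   # mm per RF sample at 1540 m/s, 20 MHz

test_that("identical frames give zero displacement at unit correlation", {
  rf <- synthesizeRF(0, nFrames = 2, nLines = 2, depthMm = 20, seed = 4)
  d <- estimateDisplacement(rf, windowLen = 64, overlap = 0.8, search = 8)
  expect_equal(max(abs(d@samples)), 0)
  expect_equal(min(d@corr), 1, tolerance = 1e-12)
})

test_that("an exact integer shift is recovered exactly", {
  rf <- synthesizeRF(function(z, k) if (k > 1) 3 * dzMm + 0 * z else 0 * z,
    nFrames = 2, nLines = 2, depthMm = 25, seed = 2)
  d <- estimateDisplacement(rf, 64, 0.8, 8)
  expect_equal(unique(round(as.numeric(d@samples), 12)), 3)
  expect_equal(as.numeric(d@mm[1, 1, 1]), 3 * dzMm)
})

test_that("sub-sample shifts agree with the 64x-upsampled correlation oracle", {
  rf <- synthesizeRF(function(z, k) if (k > 1) 0.3 * dzMm + 0 * z else 0 * z,
    nFrames = 2, nLines = 1, depthMm = 25, seed = 3)
  d <- estimateDisplacement(rf, 64, 0.8, 8)
  est <- mean(d@samples, na.rm = TRUE)
  expect_equal(est, 0.3, tolerance = 0.05)
  oracle <- upsampledShiftOracle(rf@data[1, 1, 200:500],
    rf@data[2, 1, 200:500])
  expect_equal(est, oracle, tolerance = 0.05)
})

test_that("sub-sample estimator bias stays below 0.05 samples", {
  shifts <- seq(-0.5, 0.5, by = 0.125)
  bias <- vapply(shifts, function(dd) {
    rf <- synthesizeRF(function(z, k) if (k > 1) dd * dzMm + 0 * z
      else 0 * z, nFrames = 2, nLines = 2, depthMm = 25, seed = 11)
    d <- estimateDisplacement(rf, 64, 0.8, 8)
    mean(d@samples, na.rm = TRUE) - dd
  }, numeric(1))
  expect_lt(max(abs(bias)), 0.05)
})

test_that("flat windows are flagged rather than silently zero", {
  arr <- array(0, c(2, 1, 400))
  arr[, 1, 200:400] <- rep(sin(1:201 / 3), each = 2)
  rf <- new("RFFrames", data = arr, fs = 20e6, frameRate = 2000, c = 1540)
  d <- estimateDisplacement(rf, 64, 0.5, 8)
  expect_true(anyNA(d@samples))      # flat leading region undefined
  expect_true(any(!is.na(d@samples)))
  expect_error(estimateDisplacement(rf, 4), ">= 8")
})

test_that("least-squares strain is exact for linear and constant profiles", {
  mkdisp <- function(u) new("DisplacementField",
    samples = array(u / dzMm, c(1, 1, length(u))),
    mm = array(u, c(1, 1, length(u))), corr = array(1, c(1, 1, length(u))),
    centersMm = as.numeric(seq_along(u)), fs = 20e6, c = 1540)
  lin <- estimateIncrementalStrain(mkdisp(0.01 * (1:20)), kernelMm = 5)
  expect_equal(as.numeric(lin@strain), rep(0.01, 20), tolerance = 1e-12)
  flat <- estimateIncrementalStrain(mkdisp(rep(0.3, 20)), kernelMm = 5)
  expect_equal(as.numeric(flat@strain), rep(0, 20), tolerance = 1e-12)

  # piecewise-linear: away from the breakpoint the kernel sees one slope
  u <- c(0.01 * (1:10), 0.1 + 0.03 * (1:10))
  pw <- estimateIncrementalStrain(mkdisp(u), kernelMm = 3)
  expect_equal(as.numeric(pw@strain[1, 1, 2:8]), rep(0.01, 7),
    tolerance = 1e-12)
  expect_equal(as.numeric(pw@strain[1, 1, 13:19]), rep(0.03, 7),
    tolerance = 1e-12)
  expect_error(estimateIncrementalStrain(mkdisp(0.01 * (1:20)),
    kernelMm = 0.5), "kernel")
})

test_that("the physics path recovers a known strain schedule at 20 dB SNR", {
  s0 <- 0.002
  sched <- function(z, k) (k - 1) * s0 * z
  clean <- synthesizeRF(sched, nFrames = 4, nLines = 3, depthMm = 30,
    seed = 5, scatterersPerMm = 12)
  rf <- synthesizeRF(sched, nFrames = 4, nLines = 3, depthMm = 30,
    seed = 5, scatterersPerMm = 12, noiseSd = sd(clean@data) * 10^(-20 / 20))
  d <- estimateDisplacement(rf, 64, 0.8, 8)
  s <- estimateIncrementalStrain(d, kernelMm = 5)
  profile <- apply(s@strain, 3, mean, na.rm = TRUE)
  rms <- sqrt(mean((profile - s0)^2))
  expect_lt(rms, 0.1 * s0)
})

test_that("estimated strain resamples onto mask pixels by nearest estimate", {
  m <- buildStripMask(lengthMm = 4, widthMm = 20, spacing = 1)
  vals <- seq(0.001, 0.021, by = 0.001)
  sf <- new("StrainField", strain = array(rep(vals, each = 2), c(1, 2, 21)),
    centersMm = as.numeric(0:20))
  mov <- strainToTraces(sf, m, lineX = c(0, 4), frameRate = 2000)
  expect_s4_class(mov, "StrainMovie")
  # every pixel trace equals the value at its nearest kernel center
  expect_true(all(mov@frames[1, ] %in% vals))
  i <- match(1, mov@sites$pixel)
  expect_equal(mov@frames[1, i], vals[1])
  expect_error(strainToTraces(sf, m, lineX = c(500, 504), maxDistMm = 2),
    "empty overlap")
})
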