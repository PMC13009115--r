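test_that("zero-crossing detection honours the sustained-negativity rule", {
  rate <- 2000
  t <- seq(0, 200, by = 0.5)
  # clean crossing at 40 ms
  clean <- 0.02 * tanh((40 - t) / 3)
  zc <- detectZeroCrossing(clean, rate, reference = 0, window = c(0, 200),
    smoothingMs = 0, minNegativeMs = 10)
  expect_equal(zc$quality, "accepted")
  expect_equal(zc$time, 40, tolerance = 0.25)

  # one-frame negative blip at 20 ms must be rejected; sustained from 45 ms
  blip <- rep(0.01, length(t))
  blip[t >= 20 & t < 20.5] <- -0.01
  blip[t >= 45] <- -0.01
  zb <- detectZeroCrossing(blip, rate, reference = 0, window = c(0, 200),
    smoothingMs = 0, minNegativeMs = 10)
  expect_equal(zb$time, 45, tolerance = 0.5)
  expect_equal(zb$nCandidates, 2L)
  oracle <- zcOracle(blip, rate, reference = 0, window = c(0, 200),
    smoothingMs = 0, minNegativeMs = 10)
  expect_equal(zb$time, oracle)

  # all-positive trace: no crossing, never a silent zero
  zp <- detectZeroCrossing(abs(clean) + 0.001, rate, reference = 0,
    window = c(0, 200))
  expect_equal(zp$quality, "no_crossing")
  expect_true(is.na(zp$time))
  expect_error(detectZeroCrossing(clean, rate, window = c(-50, 100)),
    "window")
})

test_that("the detector agrees with the brute-force oracle on random traces", {
  nAgree <- 0
  withr::with_seed(99, {
    for (i in 1:2000) {
      n <- 120
      tr <- cumsum(rnorm(n, 0, 0.3)) + rnorm(n) + 2 * sin(1:n / 17)
      got <- detectZeroCrossing(tr, 2000, reference = 0, window = c(0, 59),
        smoothingMs = 2, minNegativeMs = 5, startMs = 0)
      want <- zcOracle(tr, 2000, reference = 0, window = c(0, 59),
        smoothingMs = 2, minNegativeMs = 5, startMs = 0)
      same <- (is.na(got$time) && is.na(want)) ||
        (!is.na(got$time) && !is.na(want) &&
           abs(got$time - want) < 1e-9)
      nAgree <- nAgree + same
    }
  })
  expect_equal(nAgree, 2000)
})

test_that("point sampling respects the mask, strata and seed", {
  m <- buildStripMask(lengthMm = 39, widthMm = 9, spacing = 1,
    segments = c("A", "B"))
  p <- samplePoints(m, 200, "uniform", seed = 1)
  expect_equal(nrow(p), 200)
  expect_equal(anyDuplicated(p$pixel), 0)
  expect_true(all(maskGrid(m)[p$pixel]))
  expect_identical(p, samplePoints(m, 200, "uniform", seed = 1))

  # two equal-area segments: exact proportional allocation
  ps <- samplePoints(m, 200, "stratified", seed = 2)
  segs <- m@segmentLabels[m@segmentIdx[ps$pixel]]
  expect_equal(as.numeric(table(segs)), c(100, 100))
  expect_error(samplePoints(m, 2), "at least 3")
  expect_error(samplePoints(m, 1e6), "exceeds")
})

test_that("isochrone interpolation is exact, linear-precise and
          permutation-invariant", {
  m <- buildStripMask(lengthMm = 30, widthMm = 10, spacing = 0.5)
  pts <- samplePoints(m, 60, "uniform", seed = 7)
  co <- maskCoords(m, pts$pixel)

  # linear activation field reproduced to relative 1e-6 over the interior
  at <- 20 + 1.5 * co$x - 0.8 * co$y
  iso <- interpolateIsochrones(data.frame(x = co$x, y = co$y, at = at), m)
  truth <- 20 + 1.5 * maskCoords(m)$x - 0.8 * maskCoords(m)$y
  interior <- !iso@extrapolated[maskGrid(m)]
  err <- abs(iso@at[maskGrid(m)] - truth)[interior]
  expect_lt(max(err), 1e-6 * diff(range(at)))

  # exact at the sample points (curved field)
  at2 <- sin(co$x / 4) * 10 + co$y
  iso2 <- interpolateIsochrones(data.frame(x = co$x, y = co$y, at = at2), m)
  expect_equal(iso2@at[pts$pixel], at2, tolerance = 1e-12)

  # sample order is irrelevant
  p <- withr::with_seed(3, sample(nrow(pts)))
  iso3 <- interpolateIsochrones(
    data.frame(x = co$x[p], y = co$y[p], at = at2[p]), m)
  expect_equal(iso3@at, iso2@at, tolerance = 1e-9)

  # out-of-hull pixels carry the nearest sample value and the flag
  expect_true(any(iso2@extrapolated[maskGrid(m)]))
  ex <- which(iso2@extrapolated & maskGrid(m))
  expect_true(all(iso2@at[ex] %in% at2))

  expect_error(interpolateIsochrones(
    data.frame(x = c(1, 2, 3), y = c(1, 2, 3), at = 1:3), m), "collinear")
})

test_that("views co-register on the surface-ECG reference", {
  m <- buildStripMask(10, 4, spacing = 1)
  at <- matrix(NA_real_, nrow(m@mask), ncol(m@mask))
  at[maskGrid(m)] <- 100
  iso <- new("IsochroneMap", at = at,
    extrapolated = matrix(FALSE, nrow(at), ncol(at)), mask = m)
  e1 <- synthesizeECG(300, 2000, qrsOnset = 0)
  e2 <- synthesizeECG(300, 2000, qrsOnset = 12)
  reg <- registerViews(list(list(map = iso, ecg = e1),
    list(map = iso, ecg = e2)))
  expect_equal(reg[[1]]@at[maskGrid(m)], rep(100, sum(maskGrid(m))))
  expect_equal(reg[[2]]@at[maskGrid(m)], rep(88, sum(maskGrid(m))))
  expect_equal(reg[[2]]@offset, 12)

  # paced beats align on the spike
  ep <- synthesizeECG(300, 2000, qrsOnset = 40, beatType = "paced",
    pacingSpike = 30)
  regp <- registerViews(list(list(map = iso, ecg = ep)))
  expect_equal(regp[[1]]@offset, 30)

  bad <- new("ECGTrace", samples = rep(0, 100), rate = 2000,
    qrsOnset = NA_real_, pacingSpike = NA_real_, beatType = "VE")
  expect_error(registerViews(list(list(map = iso, ecg = bad))), "without")
})

test_that("SoO localization picks the global minimum across views and
          tercile layers", {
  mkIso <- function(m, atv) {
    at <- matrix(NA_real_, nrow(m@mask), ncol(m@mask))
    at[maskGrid(m)] <- atv
    new("IsochroneMap", at = at,
      extrapolated = matrix(FALSE, nrow(at), ncol(at)), mask = m)
  }
  m <- buildStripMask(lengthMm = 40, widthMm = 9, spacing = 1,
    segments = c("A", "B", "C", "D"))
  co <- maskCoords(m)

  # focal minimum at an endocardial pixel in segment B
  atv <- 40 + sqrt((co$x - 15)^2 + (co$y - 1)^2) * 2
  soo <- localizeSoO(list(mkIso(m, atv)))
  expect_equal(soo@segment, "B")
  expect_equal(soo@layer, "endo")
  expect_false(soo@diffuse)

  # second view is 8 ms earlier: the call follows it
  m2 <- buildStripMask(lengthMm = 40, widthMm = 9, spacing = 1,
    segments = c("E", "F", "G", "H"))
  atv2 <- 32 + sqrt((co$x - 35)^2 + (co$y - 8)^2) * 2
  soo2 <- localizeSoO(list(mkIso(m, atv), mkIso(m2, atv2)))
  expect_equal(soo2@segment, "H")
  expect_equal(soo2@layer, "epi")
  expect_equal(soo2@earliestTime, 32)

  # flat early plateau across 3 segments triggers the diffuse flag
  flat <- ifelse(co$x < 30, 50, 50 + (co$x - 30) * 3)
  soo3 <- localizeSoO(list(mkIso(m, flat)))
  expect_true(soo3@diffuse)
  expect_equal(soo3@layer, "diffuse")
})

test_that("the noiseless pipeline recovers segment and layer end to end", {
  for (s in 101:106) {
    ph <- makePhantomView(s)
    mv <- mapView(ph$movie, n = 300, seed = s)
    soo <- localizeSoO(registerViews(list(list(map = mv$map, ecg = mv$ecg))))
    expect_equal(soo@segment, ph$segment)
    expect_equal(soo@layer, ph$layer)
  }
})
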