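test_that("mask construction yields a valid transmural coordinate", {
  g <- viewGeometry(depthMax = 50)
  m <- buildMask(g, rEndo = 30, rEpi = 40, spacing = 0.5)
  wd <- wallDepth(m)[maskGrid(m)]
  expect_true(all(wd >= 0 & wd <= 1))

  # depth ~0 on the inner contour, ~0.5 midway (grid tolerance = spacing/wall)
  co <- maskCoords(m)
  r <- sqrt(co$x^2 + co$y^2)
  tol <- m@spacing / (40 - 30)
  expect_lt(max(wd[r < 30 + m@spacing / 2]), 2 * tol)
  expect_equal(wd[which.min(abs(r - 35))], 0.5, tolerance = 2 * tol)

  # every mask pixel carries a segment: the view partitions its mask
  expect_true(all(m@segmentIdx[maskGrid(m)] > 0))

  expect_error(buildMask(g, rEndo = 40, rEpi = 30), "degenerate")
  expect_error(buildMask(g, rEndo = 30, rEpi = 60), "inside the sector")
})

test_that("geodesic activation matches the closed form on a uniform strip", {
  m <- buildStripMask(lengthMm = 30, widthMm = 4, spacing = 1)
  f <- simulateActivation(m, sourceSpec("S1", originTime = 5, cv = 1),
    sourcePixel = c(1, 1))
  co <- maskCoords(m)
  at <- activationTimes(f)[maskGrid(m)]
  d <- sqrt(co$x^2 + co$y^2)
  # 8-connected metric paths reach any pixel within one pixel spacing of
  # the Euclidean distance on a convex strip
  expect_true(all(at >= 5 + d - 1e-9))
  expect_true(all(at <= 5 + d + m@spacing * (sqrt(2) - 1) * d + 1))
  expect_equal(activationTimes(f)[1, 1], 5)   # source pixel at origin time
})

test_that("geodesic activation equals the Dijkstra oracle, with scar", {
  scar <- list(list(poly = cbind(c(9.5, 14.5, 14.5, 9.5), c(-1, -1, 9, 9)),
    mult = 0.5))
  m <- buildStripMask(lengthMm = 24, widthMm = 6, spacing = 1)
  src <- sourceSpec("S1", originTime = 0, cv = 1, scar = scar)
  f <- simulateActivation(m, src, sourcePixel = c(3, 1))
  velocity <- function(co) ifelse(co$x >= 9.5 & co$x <= 14.5, 0.5, 1)
  oracle <- dijkstraOracle(m, c(3, 1), velocity)
  expect_equal(activationTimes(f), oracle, tolerance = 1e-12)

  # slow scar delays everything beyond it relative to homogeneous tissue
  f0 <- simulateActivation(m, sourceSpec("S1", originTime = 0, cv = 1),
    sourcePixel = c(3, 1))
  beyond <- maskCoords(m)$x > 14
  expect_true(all((activationTimes(f)[maskGrid(m)] -
    activationTimes(f0)[maskGrid(m)])[beyond] > 0))
})

test_that("disconnected mask components are flagged with undefined AT", {
  m <- buildStripMask(lengthMm = 20, widthMm = 4, spacing = 1)
  m@mask[, 10] <- FALSE   # sever the strip
  m@wallDepth[, 10] <- NA
  m@segmentIdx[, 10] <- NA_integer_
  expect_warning(
    f <- simulateActivation(m, sourceSpec("S1", cv = 1),
      sourcePixel = c(1, 1)),
    "unreachable")
  at <- activationTimes(f)
  expect_true(all(is.na(at[, 11:ncol(at)][m@mask[, 11:ncol(at)]])))
})

test_that("synthesized strain crosses zero downward at t_m within half a frame", {
  m <- buildStripMask(10, 4, spacing = 1)
  f <- simulateActivation(m, sourceSpec("S1", originTime = 10, cv = 1),
    sourcePixel = c(1, 1))
  mov <- synthesizeStrain(f, delay = 0, durationMs = 200, qrsOnsetMs = 20)
  expect_equal(1000 / frameRate(mov), 0.5)   # 0.5 ms at 2000 fps
  halfFrame <- 0.5 * 1000 / frameRate(mov) / 2 + 0.26
  for (j in c(1, 5, ncol(mov@frames))) {
    zc <- detectZeroCrossing(mov@frames[, j], frameRate(mov), reference = 0,
      window = c(0, 200), smoothingMs = 0, minNegativeMs = 10)
    expect_equal(zc$quality, "accepted")
    expect_lt(abs(zc$time - (20 + mov@sites$trueAt[j])), halfFrame)
  }
  expect_error(synthesizeStrain(f, delay = 300, durationMs = 200),
    "outside the movie duration")
})

test_that("noiseless strain round-trips the activation field at every site", {
  ph <- makePhantomView(41, segment = "S3", layer = "mid", spacing = 1.2)
  mov <- ph$movie
  qrs <- mov@ecg@qrsOnset
  ann <- annotateZeroCrossings(mov, reference = qrs,
    window = c(qrs, 300), smoothingMs = 0, minNegativeMs = 10)
  expect_true(all(ann$quality == "accepted"))
  expect_lt(max(abs(ann$at - ann$trueAt)), 0.26)  # half frame + interp slack
})

test_that("EMD subgroup models order sample means as configured", {
  n <- 20 * 24
  ms <- withr::with_seed(11, vapply(c("LGE+ve", "LVSD&LGE-ve", "normal"),
    function(g) mean(realizeDelays(emdModel(g), n)), numeric(1)))
  se <- 29 / sqrt(n)
  expect_gt(ms[["LGE+ve"]], ms[["LVSD&LGE-ve"]] - 3 * se)
  expect_gt(ms[["LVSD&LGE-ve"]], ms[["normal"]] - 3 * se)
  expect_equal(unname(ms[["LGE+ve"]]), 50, tolerance = 3 * se / 50)
})

test_that("cohort generation is reproducible and honours the subgroup split", {
  s <- cohortSpec(33, seed = 9)
  expect_identical(table(s@subgroups)[c("LGE+ve", "LVSD&LGE-ve", "normal")],
    table(factor(c(rep("LGE+ve", 20), rep("LVSD&LGE-ve", 4),
      rep("normal", 9))))[c("LGE+ve", "LVSD&LGE-ve", "normal")])
  a <- generateCohort(cohortSpec(3, seed = 5))
  b <- generateCohort(cohortSpec(3, seed = 5))
  expect_identical(serialize(a, NULL, version = 2),
    serialize(b, NULL, version = 2))
  d <- generateCohort(cohortSpec(3, seed = 6))
  expect_false(identical(serialize(a, NULL, version = 2),
    serialize(d, NULL, version = 2)))
  expect_error(cohortSpec(0), "nSubjects")
})

test_that("synthesized ECGI nodes round-trip their LAT and morphology", {
  model <- buildSegmentModel()
  segAT <- 40 + segmentDistances(model, "LV.basal.anterior") * 20
  emap <- synthesizeECGI(segAT, model, sourceLayer = "epi")
  expect_true(all(abs(emap@nodes$lat - segAT[emap@nodes$segment]) <= 1))
  expect_true(all(vapply(emap@uegms, classifyMorphology,
    character(1)) == "QS"))
  emapRs <- synthesizeECGI(segAT, model, sourceLayer = "endo")
  expect_true(all(vapply(emapRs@uegms, classifyMorphology,
    character(1)) == "rS"))
  expect_error(synthesizeECGI(segAT, model,
    segments = "LV.basal.anteroseptal"), "septal")
})

test_that("RF synthesis repeats frames under a zero schedule and states
          its axial spacing", {
  rf <- synthesizeRF(0, nFrames = 3, nLines = 2, depthMm = 15, seed = 8)
  expect_equal(rf@data[1, , ], rf@data[2, , ])
  expect_equal(rf@data[2, , ], rf@data[3, , ])
  expect_equal(axialSampleSpacing(1540, 20e6), 0.0385)
  expect_error(synthesizeRF(0, fs = 5e6), "4x")
})
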