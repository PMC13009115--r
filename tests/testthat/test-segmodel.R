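model <- buildSegmentModel()

test_that("the biventricular model has 24 segments with correct coverage
          flags", {
  expect_equal(nrow(model), 24)
  expect_equal(sum(model$chamber == "LV"), 16)
  expect_equal(sum(model$chamber == "RV"), 8)
  expect_equal(as.numeric(table(model$level[model$chamber == "LV"])
    [c("basal", "mid", "apical")]), c(6, 6, 4))
  expect_equal(as.numeric(table(model$level[model$chamber == "RV"])
    [c("basal", "mid", "apical")]), c(3, 3, 2))
  expect_equal(sum(model$septal), 6)
  expect_equal(sum(model$septal & model$chamber == "LV"), 5)
  expect_identical(model$ecgiCovered, !model$septal)

  # the view allocation partitions all 24 segments
  vs <- viewSegmentMap()
  expect_equal(sort(unname(unlist(vs))), sort(model$segment))
  expect_equal(anyDuplicated(unlist(vs)), 0)

  # adjacency connects the whole heart
  expect_true(all(is.finite(segmentDistances(model, "LV.apical.septal"))))
})

test_that("bullseye extraction averages epicardial samples per segment", {
  uni <- data.frame(segment = rep(model$segment, each = 3), at = 100,
    wallDepth = 0.9)
  be <- extractBullseye(uni, model, modality = "EWI")
  expect_equal(unname(bullseyeValues(be)), rep(100, 24))

  # EWI restriction: sub-epicardial samples are ignored
  mix <- rbind(uni, data.frame(segment = model$segment, at = 0,
    wallDepth = 0.1))
  expect_equal(unname(bullseyeValues(extractBullseye(mix, model))),
    rep(100, 24))

  # ECGI coverage masks septal segments
  segAT <- stats::setNames(rep(60, 24), model$segment)
  emap <- synthesizeECGI(segAT, model)
  beE <- extractBullseye(emap, model)
  expect_true(all(is.na(bullseyeValues(beE)[model$segment[model$septal]])))
  expect_true(all(!is.na(bullseyeValues(beE)[model$segment[!model$septal]])))
  # coverage conservation
  expect_equal(sum(is.na(bullseyeValues(beE))) +
    sum(!is.na(bullseyeValues(beE))), 24)
  expect_warning(extractBullseye(uni[uni$segment != "LV.basal.anterior", ],
    model), "masked")
})

test_that("segment means of a linear field match analytic area-weighted
          means", {
  g <- viewGeometry(depthMax = 50, sectorAngle = 90)
  m <- buildMask(g, rEndo = 30, rEpi = 40, spacing = 0.25,
    segments = c("LV.basal.anterior", "LV.basal.inferior",
      "LV.mid.anterior", "LV.mid.inferior"))
  b <- 2  # ms per mm along x
  idx <- which(maskGrid(m))
  co <- maskCoords(m, idx)
  iso <- new("IsochroneMap",
    at = {a <- matrix(NA_real_, nrow(m@mask), ncol(m@mask))
          a[idx] <- 50 + b * co$x; a},
    extrapolated = matrix(FALSE, nrow(m@mask), ncol(m@mask)), mask = m)
  be <- suppressWarnings(extractBullseye(iso, model))  # 20 segments off-view
  # analytic mean of x over an annular sector (polar integration), for the
  # epicardial band r in [rEndo + 2/3 w, rEpi], theta in the sector quarter
  r1 <- 30 + 2 / 3 * 10; r2 <- 40
  meanX <- function(th1, th2) {
    (diff(c(cos(th2), cos(th1))) * (r2^3 - r1^3) / 3) /
      ((th2 - th1) * (r2^2 - r1^2) / 2)
  }
  # x = r sin(theta), theta measured from vertical; segment sectors are
  # quarters of the 90-degree span starting at -45 degrees
  th <- seq(-pi / 4, pi / 4, length.out = 5)
  want <- 50 + b * vapply(1:4, function(k) meanX(th[k], th[k + 1]),
    numeric(1))
  got <- unname(bullseyeValues(be)[c("LV.basal.anterior",
    "LV.basal.inferior", "LV.mid.anterior", "LV.mid.inferior")])
  expect_equal(got, want, tolerance = 0.02)
})

test_that("EMD deltas are zero on self, anti-symmetric, and carry the sign
          convention", {
  v <- stats::setNames(withr::with_seed(2, rnorm(24, 100, 20)),
    model$segment)
  beA <- new("SegmentBullseye", values = v, modality = "EWI", subject = "s")
  beB <- new("SegmentBullseye", values = v - 45, modality = "ECGI",
    subject = "s")
  self <- computeEMD(beA, beA, model)
  expect_true(all(self$delta == 0))
  ab <- computeEMD(beA, beB, model)
  ba <- computeEMD(beB, beA, model)
  expect_equal(ab$delta, -ba$delta)
  # ECGI uniformly 45 ms earlier: mean 45, SD 0, all positive
  expect_equal(attr(ab, "meanDelta"), 45)
  expect_equal(attr(ab, "sdDelta"), 0)
  expect_equal(attr(ab, "fracPositive"), 1)

  beC <- new("SegmentBullseye",
    values = stats::setNames(rep(NA_real_, 24), model$segment),
    modality = "ECGI", subject = "s")
  expect_error(computeEMD(beA, beC, model), "jointly covered")
})

test_that("subgroup analysis recovers configured cell means and is
          order-invariant", {
  mkTable <- function() {
    subj <- sprintf("s%02d", 1:33)
    sg <- c(rep("LGE+ve", 20), rep("LVSD&LGE-ve", 4), rep("normal", 9))
    mu <- c("LGE+ve" = 50, "LVSD&LGE-ve" = 39, "normal" = 33)
    sdv <- c("LGE+ve" = 29, "LVSD&LGE-ve" = 25, "normal" = 21)
    do.call(rbind, lapply(1:33, function(i) {
      data.frame(subject = subj[i], segment = model$segment,
        level = model$level, chamber = model$chamber,
        delta = rnorm(24, mu[sg[i]], sdv[sg[i]]), subgroup = sg[i])
    }))
  }
  tab <- withr::with_seed(12, mkTable())
  sa <- subgroupAnalysis(tab)
  cells <- sa$cells
  getCell <- function(r, cl) cells$mean[cells$row == r & cells$column == cl]
  for (g in c("LGE+ve", "LVSD&LGE-ve", "normal")) {
    n <- sum(tab$subgroup == g)
    mu <- c("LGE+ve" = 50, "LVSD&LGE-ve" = 39, "normal" = 33)[[g]]
    sdv <- c("LGE+ve" = 29, "LVSD&LGE-ve" = 25, "normal" = 21)[[g]]
    expect_equal(getCell("Global", g), mu, tolerance = 3 * sdv / sqrt(n) / mu)
  }
  # separated subgroups: the global ANOVA and LGE+ve vs normal post-hoc fire
  expect_lt(sa$anovaP[["Global"]], 0.001)
  expect_lt(sa$pairwiseP["normal", "LGE+ve"], 0.001)

  perm <- withr::with_seed(4, tab[sample(nrow(tab)), ])
  sa2 <- subgroupAnalysis(perm)
  expect_equal(sa2$cells$mean, sa$cells$mean)
  expect_equal(sa2$anovaP, sa$anovaP)

  one <- tab[tab$subgroup == "normal", ]
  sa1 <- subgroupAnalysis(one)
  expect_true(is.na(sa1$anovaP[["Global"]]))
  expect_false(any(is.na(sa1$cells$mean[sa1$cells$column == "All"])))
})

test_that("the subgroup ANOVA holds its type-I error under the null", {
  nRej <- withr::with_seed(77, {
    sg <- rep(c(rep("LGE+ve", 20), rep("LVSD&LGE-ve", 4), rep("normal", 9)),
      each = 18)
    lev <- rep(sample(model$level[model$ecgiCovered]), 33)
    ch <- rep(sample(model$chamber[model$ecgiCovered]), 33)
    sum(replicate(500, {
      tab <- data.frame(subject = rep(1:33, each = 18),
        segment = "x", level = lev, chamber = ch,
        delta = rnorm(33 * 18, 45, 28), subgroup = sg)
      subgroupAnalysis(tab)$anovaP[["Global"]] < 0.05
    }))
  })
  expect_gt(nRej / 500, 0.03)
  expect_lt(nRej / 500, 0.07)
})

test_that("localization scoring matches a hand counter and chance level", {
  est <- data.frame(map = sprintf("m%d", 1:10),
    ewiSegment = model$segment[1:10], ewiLayer = rep("endo", 10),
    ewiDiffuse = FALSE, ecgiSegment = model$segment[1:10])
  truth <- data.frame(map = sprintf("m%d", 1:10),
    segment = model$segment[1:10], layer = "endo")
  sc <- scoreLocalization(est, truth, model)
  agg <- aggregateLocalization(sc)
  expect_equal(agg$ewiSegment$pct, 100)
  expect_equal(agg$bothFailed$pct, 0)
  expect_equal(agg$agreementCorrect$pct, 100)

  # diffuse counts as axially incorrect even with the right layer
  est2 <- est; est2$ewiDiffuse[1] <- TRUE
  agg2 <- aggregateLocalization(scoreLocalization(est2, truth, model))
  expect_equal(agg2$ewiAxial$pct, 90)

  expect_error(scoreLocalization(est,
    transform(truth, segment = "nope"), model), "not in the model")

  # random calls vs uniform truth: accuracy ~ 1/24
  big <- withr::with_seed(8, {
    n <- 10000
    est3 <- data.frame(map = seq_len(n),
      ewiSegment = sample(model$segment, n, TRUE),
      ewiLayer = sample(c("endo", "mid", "epi"), n, TRUE),
      ewiDiffuse = FALSE,
      ecgiSegment = sample(model$segment, n, TRUE))
    truth3 <- data.frame(map = seq_len(n),
      segment = sample(model$segment, n, TRUE),
      layer = sample(c("endo", "mid", "epi"), n, TRUE))
    aggregateLocalization(scoreLocalization(est3, truth3, model))
  })
  p <- 1 / 24
  tol <- 3 * sqrt(p * (1 - p) / 10000) * 100
  expect_equal(big$ewiSegment$pct, 100 * p, tolerance = tol / (100 * p))

  # aggregates recompute from the booleans (brute-force counter)
  sc3 <- withr::with_seed(9, data.frame(map = 1:50,
    layer = sample(c("endo", "mid", "epi"), 50, TRUE),
    ewiCorrect = sample(c(TRUE, FALSE, NA), 50, TRUE, c(.45, .45, .1)),
    ecgiCorrect = sample(c(TRUE, FALSE), 50, TRUE),
    ewiAxialCorrect = sample(c(TRUE, FALSE), 50, TRUE)))
  agg3 <- aggregateLocalization(sc3)
  expect_equal(agg3$ewiSegment$pct,
    100 * sum(sc3$ewiCorrect %in% TRUE) / sum(!is.na(sc3$ewiCorrect)))
  nBoth <- 0
  for (i in 1:50)
    if (!is.na(sc3$ewiCorrect[i]) && !sc3$ewiCorrect[i] &&
        !sc3$ecgiCorrect[i]) nBoth <- nBoth + 1
  expect_equal(agg3$bothFailed$pct, 100 * nBoth / 50)
  expect_equal(agg3$ewiSegment$ci[1] <= agg3$ewiSegment$pct, TRUE)
})
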