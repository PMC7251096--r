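# The synthetic plate simulator and its ground truth.

test_that("death schedules are reproducible and follow the distribution", {
  cfg <- SimConfig(nPlates = 2, nWorms = 5, lifespanSd = 0)
  d <- scheduleDeaths(cfg, seed = 1)
  expect_true(all(d == 14))
  cfg2 <- SimConfig(nPlates = 100, nWorms = 100)
  d1 <- scheduleDeaths(cfg2, seed = 5)
  d2 <- scheduleDeaths(cfg2, seed = 5)
  expect_identical(d1, d2)
  expect_lt(abs(mean(d1) - 14) / 14, 0.01)   # 10,000 draws
  expect_true(all(d1 >= cfg2@headOnlyDays + 1))
})

test_that("worm displacement decays with age and stops at death", {
  cfg <- SimConfig()
  start <- c(100, 100, 0.3, 0, 0, 2)
  disp <- vapply(c(0, 0.4, 0.8), function(a) {
    k <- simulateWormKinematics(start, a, cfg, seed = 3)
    mean(sqrt(rowSums(diff(k[, 1:2])^2)))
  }, 1)
  expect_true(all(diff(disp) < 0))
  expect_gt(disp[1], 0.9 * cfg@maxStepPerFrame)
  dead <- simulateWormKinematics(start, 1, cfg, seed = 3, state = "dead")
  expect_true(all(dead == matrix(rep(start, each = cfg@nFramesPerDay),
                                 ncol = 6)))
  head <- simulateWormKinematics(start, 1, cfg, seed = 3, state = "headOnly")
  expect_true(all(head[, 1:2] == matrix(start[1:2], nrow(head), 2,
                                        byrow = TRUE)))
  expect_gt(stats::sd(head[, 5]), 0)   # the head itself moves
})

test_that("rendered frames have the configured photometry", {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 0, nDays = 1, seed = 6)
  assay <- simulateAssay(cfg)
  img <- frames(frameSequence(assay, 1, 0))[, , 1]
  ## background mode at 48
  expect_equal(as.integer(names(which.max(table(round(img))))), 48)
  ## dark pixels only near the wall annulus / outside the plate (the
  ## rings wobble inward by up to ~3 px)
  geom <- wormspan:::plateGeometry(cfg)
  rr <- sqrt(outer((seq_len(486) - geom$center[1])^2,
                   (seq_len(486) - geom$center[2])^2, "+"))
  dark <- img < 33
  expect_true(all(rr[dark] > geom$centerRadius - 5))
})

test_that("a rendered worm lands inside the matched model's area band", {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 1, nDays = 1, seed = 8)
  model <- simWormModel(cfg)
  set.seed(2)
  for (i in 1:10) {
    n <- 60L
    tmp <- cfg; tmp@imageSize <- n
    pose <- c(30, 30, runif(1, 0, pi), runif(1, 0, 2 * pi), 0,
              cfg@wormAmp * runif(1, 0.7, 1.2))
    sil <- renderPlateFrame(tmp, matrix(pose, 1), base = matrix(48, n, n),
                            silhouette = TRUE)$silhouette
    expect_gte(sum(sil), model@minArea)
    expect_lte(sum(sil), model@maxArea)
    ## worm pixels darker than the worm ceiling, well below threshold
    img <- renderPlateFrame(tmp, matrix(pose, 1),
                            base = matrix(48, n, n))
    expect_lt(mean(img[sil]), 20)
  }
})

test_that("hidden worms leave no dark pixels in the plate centre", {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 1, nDays = 1, seed = 12,
                        noiseSd = 0)
  assay <- simulateAssay(cfg)
  assay@hidden[1, 1, 1] <- TRUE
  img <- frames(frameSequence(assay, 1, 0))[, , 1]
  cm <- classifyPixels(stackSignatures(frameSequence(assay, 1, 0)))
  z <- detectZones(cm)
  expect_equal(sum(img < 33 & centerMask(z)), 0)
})

test_that("the same seed reproduces the assay bit for bit", {
  cfg <- SimConfig(nPlates = 1, nWorms = 3, nDays = 2, imageSize = 200,
                   seed = 31)
  a1 <- simulateAssay(cfg)
  a2 <- simulateAssay(cfg)
  expect_identical(a1@deathDays, a2@deathDays)
  expect_identical(a1@poses, a2@poses)
  f1 <- frames(frameSequence(a1, 1, 1))
  f2 <- frames(frameSequence(a2, 1, 1))
  expect_identical(f1, f2)
})

test_that("ground-truth live counts never increase", {
  cfg <- SimConfig(nPlates = 4, nWorms = 8, nDays = 25, seed = 2)
  assay <- simulateAssay(cfg)
  for (p in 1:4) expect_true(all(diff(assay@trueCounts[p, ]) <= 0))
  tc <- trueCurves(assay)
  expect_equal(length(tc), 4L)
  expect_equal(curveCounts(tc[[2]]), assay@trueCounts[2, ])
})

test_that("the wall shadow covers about 7% of the plate", {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 0, nDays = 1, seed = 3)
  assay <- simulateAssay(cfg)
  cm <- classifyPixels(stackSignatures(frameSequence(assay, 1, 0)))
  z <- detectZones(cm)
  geom <- wormspan:::plateGeometry(cfg)
  plateArea <- pi * geom$plateRadius^2
  shadowFrac <- (plateArea - sum(centerMask(z))) / plateArea
  expect_gt(shadowFrac, 0.06)
  expect_lt(shadowFrac, 0.08)
})

test_that("worm photometry ordering holds: worm < threshold < background", {
  cfg <- SimConfig()
  expect_lt(cfg@wormIntensity, 20)
  expect_lt(cfg@ringIntensity, 33)
  expect_gt(cfg@backgroundLevel, 33)
  expect_error(SimConfig(wormIntensity = 25))
  expect_error(SimConfig(hidingProb = 1.5))
})
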