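test_that("fixed-threshold segmentation uses a strict boundary", {
  cfg <- SegmentationConfig()
  f <- matrix(c(0, 32, 33, 48, 255, 20), 2, 3)
  m <- segmentFrame(f, cfg)
  expect_identical(as.vector(m), c(1L, 1L, 0L, 0L, 0L, 1L))
  expect_error(segmentFrame(array(0, c(2, 2, 2))), "2-D")
  expect_error(segmentFrame(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("segmentation is idempotent on its own output as an image", {
  cfg <- SegmentationConfig()
  set.seed(1)
  f <- matrix(runif(400, 0, 255), 20)
  m <- segmentFrame(f, cfg)
  asImage <- matrix(ifelse(m == 1L, 0, 255), 20)   # dark -> 0, white -> 255
  expect_identical(segmentFrame(asImage, cfg), m)
})

test_that("signature stacking matches per-frame segmentation", {
  cfg <- SegmentationConfig()
  fr <- replicate(5, matrix(48, 6, 6), simplify = FALSE)
  fr[[2]][3, 4] <- 10
  seq <- FrameSequence(fr)
  st <- stackSignatures(seq, cfg)
  expect_equal(dim(st)[3], 5)
  expect_equal(st[3, 4, ], c(0, 1, 0, 0, 0))
  expect_true(all(st[, , 1] == segmentFrame(fr[[1]], cfg)))
  expect_error(FrameSequence(list(matrix(48, 4, 4), matrix(48, 5, 5))),
               "dimensions")
})

test_that("signature classification separates constant, motion, noise", {
  cfg <- SegmentationConfig()
  expect_equal(classifySignature(rep(1, 30), cfg), "CONSTANT_DARK")
  expect_equal(classifySignature(rep(0, 30), cfg), "CONSTANT_WHITE")
  expect_equal(classifySignature(c(rep(1, 15), rep(0, 15)), cfg), "MOTION")
  expect_equal(classifySignature(rep(0:1, 15), cfg), "NOISY")
  expect_error(classifySignature(1, cfg), "length")
})

test_that("signature classification is invariant to temporal reversal", {
  cfg <- SegmentationConfig()
  set.seed(42)
  for (i in 1:200) {
    s <- rbinom(sample(5:30, 1), 1, runif(1))
    expect_identical(classifySignature(s, cfg),
                     classifySignature(rev(s), cfg))
  }
})

test_that("pixel classification partitions the image", {
  cfg <- SegmentationConfig()
  set.seed(7)
  stack <- array(rbinom(12 * 12 * 10, 1, 0.4), c(12, 12, 10))
  cm <- classifyPixels(stack, cfg)
  lab <- classLabels(cm)
  expect_true(all(lab %in% pixelClasses))
  expect_equal(length(lab), 12 * 12)
  ## agreement with the scalar classifier on every pixel
  for (idx in sample(144, 25)) {
    r <- (idx - 1) %% 12 + 1; c <- (idx - 1) %/% 12 + 1
    expect_equal(names(pixelClasses)[match(lab[r, c], pixelClasses)],
                 classifySignature(stack[r, c, ], cfg))
  }
  ## a fully static sequence contains only constant labels
  static <- array(rep(matrix(rbinom(144, 1, 0.3), 12), 10), c(12, 12, 10))
  lab2 <- classLabels(classifyPixels(static, cfg))
  expect_true(all(lab2 %in% pixelClasses[c("CONSTANT_DARK", "CONSTANT_WHITE")]))
})

test_that("zone detection picks the max-area white blob and fills holes", {
  w <- pixelClasses[["CONSTANT_WHITE"]]; d <- pixelClasses[["CONSTANT_DARK"]]
  lab <- matrix(d, 40, 40)
  ## small filled disc (area ~ 150) vs larger-extent thin ring (area ~ 100)
  rr <- sqrt(outer((1:40 - 12)^2, (1:40 - 12)^2, "+"))
  lab[rr < 7] <- w
  ring <- sqrt(outer((1:40 - 28)^2, (1:40 - 28)^2, "+"))
  lab[ring > 10 & ring < 11.5] <- w
  lab[12, 12] <- d                       # a worm punches a hole
  z <- detectZones(classMapFrom(lab))
  expect_true(centerMask(z)[12, 12])     # hole filled
  expect_true(centerMask(z)[12, 13])
  expect_false(centerMask(z)[28, 38])    # ring not selected (smaller area)
  expect_true(all(!(centerMask(z) & wallMask(z))))
  expect_error(detectZones(classMapFrom(matrix(d, 5, 5))), "no plate centre")
})

test_that("constant-dark pixels are recoded by zone, other labels kept", {
  d <- pixelClasses[["CONSTANT_DARK"]]
  lab <- matrix(pixelClasses[["CONSTANT_WHITE"]], 10, 10)
  lab[2, 2] <- d; lab[9, 9] <- d; lab[5, 5] <- pixelClasses[["MOTION"]]
  center <- matrix(FALSE, 10, 10); center[4:10, 4:10] <- TRUE
  cm2 <- recodeDarkByZone(classMapFrom(lab), zonesFrom(center))
  lab2 <- classLabels(cm2)
  expect_equal(lab2[2, 2], pixelClasses[["CONSTANT_DARK_WALL"]])
  expect_equal(lab2[9, 9], pixelClasses[["CONSTANT_DARK_CENTER"]])
  expect_equal(lab2[5, 5], pixelClasses[["MOTION"]])
  expect_equal(length(lab2), length(lab))   # relabel only
  expect_error(recodeDarkByZone(classMapFrom(lab),
                                zonesFrom(matrix(TRUE, 5, 5))), "mismatch")
})

test_that("detected plate centre covers ~93% of the plate area", {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 3, nDays = 1, seed = 2)
  assay <- simulateAssay(cfg)
  fs <- frameSequence(assay, 1, 0)
  cm <- classifyPixels(stackSignatures(fs))
  z <- detectZones(cm)
  geom <- wormspan:::plateGeometry(cfg)
  plateArea <- pi * geom$plateRadius^2
  frac <- sum(centerMask(z)) / plateArea
  expect_gt(frac, 0.90)
  expect_lt(frac, 0.96)
})

test_that("motion labels recover the moving-worm footprint on clean renders", {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 4, nDays = 1, seed = 5,
                        noiseSd = 0)
  assay <- simulateAssay(cfg)
  out <- frameSequence(assay, 1, 0, withTruth = TRUE)
  cm <- classifyPixels(stackSignatures(out$seq))
  lab <- classLabels(cm)
  motion <- lab == pixelClasses[["MOTION"]]
  ## ground truth: worm pixels dark in some but not all frames
  anyS <- Reduce(`|`, out$silhouettes)
  allS <- Reduce(`&`, out$silhouettes)
  truth <- anyS & !allS
  jac <- sum(motion & truth) / sum(motion | truth)
  expect_gte(jac, 0.99)
})
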