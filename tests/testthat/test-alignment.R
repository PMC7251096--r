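# Inter-day rigid alignment and quiescent-worm death checks.

alignFixture <- function(seed = 7) {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 5, nDays = 2, seed = seed,
                        nFramesPerDay = 2)
  list(cfg = cfg, assay = simulateAssay(cfg),
       mcfg = MotionConfig(scale = cfg@scale))
}

test_that("identical day images give the identity transform", {
  fx <- alignFixture()
  fs <- frameSequence(fx$assay, 1, 0)
  tf <- alignDays(fs, fs, fx$mcfg)
  expect_equal(tf@angle, 0)
  expect_equal(c(tf@tx, tf@ty), c(0, 0), tolerance = 1e-6)
})

test_that("synthetic shifts and rotations are recovered", {
  fx <- alignFixture()
  fs0 <- frameSequence(fx$assay, 1, 0)
  perturb <- function(ang, tx, ty) {
    a2 <- fx$assay
    a2@transforms[1, 1, ] <- c(ang, tx, ty)
    frameSequence(a2, 1, 0)
  }
  tf <- alignDays(perturb(0, 10, -7), fs0, fx$mcfg)
  expect_lt(abs(tf@tx - 10), 1)
  expect_lt(abs(tf@ty + 7), 1)
  tf2 <- alignDays(perturb(3, 0, 0), fs0, fx$mcfg)
  expect_lt(abs(tf2@angle - 3), 0.5)
  expect_lt(sqrt(tf2@tx^2 + tf2@ty^2), 1)
  expect_error(alignDays(
    FrameSequence(array(48, c(10, 10, 2))),
    FrameSequence(array(48, c(12, 12, 2))), fx$mcfg), "mismatch")
})

test_that("rigid transform inversion is a true inverse", {
  set.seed(2)
  for (i in 1:20) {
    tf <- RigidTransform(runif(1, -5, 5), runif(1, -20, 20), runif(1, -20, 20))
    inv <- wormspan:::invertTransform(tf, c(100, 100))
    pts <- matrix(runif(10, 1, 100), 5, 2)
    back <- wormspan:::transformPoints(
      wormspan:::transformPoints(pts, tf, c(100, 100)), inv, c(100, 100))
    expect_equal(back, pts, tolerance = 1e-8)
  }
})

test_that("quiescent-worm death check compares sub-masks across days", {
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 1, nDays = 1, seed = 3)
  n <- 80L
  tmp <- cfg; tmp@imageSize <- n
  draw <- function(r, c, phi) renderPlateFrame(
    tmp, matrix(c(r, c, phi, 0.4, 0, 2), 1), base = matrix(48, n, n),
    silhouette = TRUE)
  today <- draw(40, 40, 0.8)
  blob <- blobFromMask(today$silhouette, today$img)
  track <- new("WormTrack", blobs = list(blob), frames = 1L,
               motionState = "QUIESCENT")
  mcfg <- MotionConfig(scale = 1)
  id <- RigidTransform()
  ## identical previous frame: unchanged shape, dead
  res <- detectInterdayMotion(track, today$img, today$img, id, mcfg)
  expect_false(res$alive)
  expect_gte(res$score, 0.99)
  ## worm was elsewhere yesterday: empty window, alive
  prevEmpty <- matrix(48, n, n)
  res2 <- detectInterdayMotion(track, today$img, prevEmpty, id, mcfg)
  expect_true(res2$alive)
  ## worm re-curled and shifted since yesterday: alive
  prevMoved <- draw(46, 44, 2.2)$img
  res3 <- detectInterdayMotion(track, today$img, prevMoved, id, mcfg)
  expect_true(res3$alive)
})

test_that("a true rigid displacement is compensated in the death check", {
  ## dead worm, but the plate moved between days: with the recovered
  ## transform the masks still match and the worm stays dead
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 4, nDays = 2, seed = 13,
                        lifespanSd = 0, lifespanMean = 1,
                        headOnlyDays = 0)    # all worms dead from day 1
  assay <- simulateAssay(cfg)
  assay@transforms[1, 2, ] <- c(1.5, 6, -4)
  pcfg <- simPipelineConfig(cfg)
  r0 <- processPlateDay(frameSequence(assay, 1, 0), pcfg)
  r1 <- processPlateDay(frameSequence(assay, 1, 1), pcfg, r0$state)
  expect_equal(liveTotal(r1$liveCount), 0L)
})
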