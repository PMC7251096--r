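# Worm-level tracking and motion classification.

# A blob at integer position (r, c) with a 3x3 square footprint.
sqBlob <- function(r, c, t, dm = c(60L, 60L)) {
  rc <- as.matrix(expand.grid(r + (-1:1), c + (-1:1)))
  px <- (rc[, 2] - 1L) * dm[1] + rc[, 1]
  new("WormBlob", pixels = as.integer(px), dim = dm, area = 9,
      centroid = c(r, c), meanIntensity = 10, frameIndex = as.integer(t))
}

test_that("a drifting worm with overlap forms one track", {
  perFrame <- lapply(1:20, function(t) list(sqBlob(10 + t, 10, t)))
  tr <- trackWorms(perFrame)
  expect_length(tr, 1L)
  expect_length(tr[[1]]@blobs, 20L)
})

test_that("two never-overlapping worms keep separate identities", {
  perFrame <- lapply(1:15, function(t)
    list(sqBlob(10 + t, 10, t), sqBlob(40 - t, 40, t)))
  tr <- trackWorms(perFrame)
  expect_length(tr, 2L)
  ## identities never swap: column stays constant within each track
  cols <- lapply(tr, function(x) vapply(x@blobs, function(b) b@centroid[2], 1))
  expect_true(all(vapply(cols, function(c) length(unique(c)) == 1L, TRUE)))
})

test_that("a blob appearing once forms its own 1-blob track", {
  perFrame <- c(rep(list(list()), 9), list(list(sqBlob(20, 20, 10))),
                rep(list(list()), 9))
  tr <- trackWorms(perFrame)
  expect_length(tr, 1L)
  expect_length(tr[[1]]@blobs, 1L)
})

test_that("a one-frame detection gap does not split a track", {
  perFrame <- lapply(1:10, function(t)
    if (t == 5) list() else list(sqBlob(10, 10 + t, t)))
  tr <- trackWorms(perFrame)
  expect_length(tr, 1L)
  expect_length(tr[[1]]@blobs, 9L)
})

test_that("motion classification uses displacement or footprint change", {
  cfg <- MotionConfig(minCentroidDisplacement = 5, scale = 1)
  static <- new("WormTrack", blobs = lapply(1:30, function(t) sqBlob(10, 10, t)),
                frames = 1:30)
  expect_equal(motionState(classifyTrackMotion(static, cfg)), "QUIESCENT")
  moving <- new("WormTrack",
                blobs = lapply(1:30, function(t) sqBlob(10 + t, 10, t)),
                frames = 1:30)
  expect_equal(motionState(classifyTrackMotion(moving, cfg)), "MOTION")
  ## footprint turnover without centroid displacement: an L-shape whose
  ## pixels migrate around a fixed centroid
  mkL <- function(t, flip) {
    base <- if (flip) expand.grid(8:12, 10) else expand.grid(10, 8:12)
    px <- (base[, 2] - 1L) * 60L + base[, 1]
    new("WormBlob", pixels = as.integer(px), dim = c(60L, 60L), area = 5,
        centroid = c(10, 10), meanIntensity = 10, frameIndex = as.integer(t))
  }
  wiggler <- new("WormTrack",
                 blobs = lapply(1:10, function(t) mkL(t, t > 5)),
                 frames = 1:10)
  expect_equal(motionState(classifyTrackMotion(wiggler, cfg)), "MOTION")
})
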