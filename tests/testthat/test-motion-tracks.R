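# Wall-zone bridging, pixel-track labelling and zone classification.

# A classmap with a wall annulus of dark ring, plus optional motion pixels.
wallScene <- function(n = 80) {
  w <- pixelClasses
  lab <- matrix(w[["CONSTANT_WHITE"]], n, n)
  center <- matrix(FALSE, n, n)
  center[, 1:40] <- TRUE                       # left half = centre
  lab[, 45:47] <- w[["CONSTANT_DARK_WALL"]]    # a dark ring band
  list(lab = lab, zones = zonesFrom(center))
}

test_that("wall motion is bridged through dark rings but never white", {
  sc <- wallScene()
  lab <- sc$lab
  ## two motion fragments touching the dark band, 40 px apart along it
  ## and on opposite sides of the ring: the geodesic dilation runs along
  ## and across the dark pixels and joins them
  lab[10, 44] <- pixelClasses[["MOTION"]]
  lab[50, 48] <- pixelClasses[["MOTION"]]
  ## a second pair separated by pure white: must stay apart
  lab[70, 55] <- pixelClasses[["MOTION"]]
  lab[78, 55] <- pixelClasses[["MOTION"]]
  cm <- classMapFrom(lab)
  br <- dilateWallMotion(cm, sc$zones, TrackConfig(wallDilationRadius = 40))
  comp <- wormspan:::label8(br)
  expect_equal(comp[10, 44], comp[50, 48])   # bridged along/across the ring
  expect_false(comp[70, 55] == comp[78, 55]) # white gap not crossed
  expect_error(dilateWallMotion(cm, sc$zones, TrackConfig(-1)))
})

test_that("no wall motion leaves the motion mask unchanged", {
  sc <- wallScene()
  lab <- sc$lab
  lab[10, 10] <- pixelClasses[["MOTION"]]    # centre-zone motion only
  br <- dilateWallMotion(classMapFrom(lab), sc$zones, TrackConfig(10))
  expect_identical(br, lab == pixelClasses[["MOTION"]])
})

test_that("pixel tracks use zone-dependent connectivity and need motion", {
  sc <- wallScene()
  lab <- sc$lab
  ## centre: quiescent dark blob touching a moving blob -> one track
  lab[10:12, 5] <- pixelClasses[["CONSTANT_DARK_CENTER"]]
  lab[13:14, 5] <- pixelClasses[["MOTION"]]
  ## centre: isolated quiescent blob -> no track
  lab[30:33, 10] <- pixelClasses[["CONSTANT_DARK_CENTER"]]
  ## wall: two disjoint motion arcs
  lab[20, 50] <- pixelClasses[["MOTION"]]
  lab[70, 50] <- pixelClasses[["MOTION"]]
  cm <- classMapFrom(lab)
  br <- dilateWallMotion(cm, sc$zones, TrackConfig(5))
  tracks <- labelPixelTracks(cm, sc$zones, br)
  zc <- vapply(tracks, zoneClass, "")
  expect_equal(sum(zc == "WALL"), 2)
  expect_equal(sum(zc == "CENTER"), 1)
  ctr <- tracks[[which(zc == "CENTER")[1]]]
  expect_equal(length(ctr@pixels), 5)        # dark + motion merged
  expect_equal(ctr@nMotionPixels, 2L)
  ## the isolated quiescent blob emitted no track
  expect_equal(length(tracks), 3L)
})

test_that("track zone classification: WALL, CENTER, MIXED", {
  center <- matrix(FALSE, 10, 10); center[, 1:5] <- TRUE
  z <- zonesFrom(center)
  mk <- function(px) new("PixelTrack", pixels = as.integer(px),
                         dim = c(10L, 10L), zoneClass = "MIXED",
                         nMotionPixels = 1L)
  expect_equal(zoneClass(classifyTrackZone(mk(c(1, 2)), z)), "CENTER")
  expect_equal(zoneClass(classifyTrackZone(mk(c(95, 96)), z)), "WALL")
  expect_equal(zoneClass(classifyTrackZone(mk(c(2, 95)), z)), "MIXED")
})

test_that("raising the dilation radius never increases wall track count", {
  sc <- wallScene()
  lab <- sc$lab
  set.seed(3)
  wallCols <- 41:55
  for (k in 1:12) lab[sample(80, 1), sample(wallCols, 1)] <-
    pixelClasses[["MOTION"]]
  cm <- classMapFrom(lab)
  counts <- vapply(c(2, 5, 10, 20, 40), function(r) {
    br <- dilateWallMotion(cm, sc$zones, TrackConfig(r))
    tr <- labelPixelTracks(cm, sc$zones, br)
    sum(vapply(tr, zoneClass, "") == "WALL")
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("worms moving in the wall ring are counted as wall tracks", {
  ## three worms placed tangentially in the wall annulus, far apart
  cfg <- cleanSimConfig(nPlates = 1, nWorms = 1, nDays = 1, seed = 4)
  geom <- wormspan:::plateGeometry(cfg)
  n <- cfg@imageSize
  midR <- mean(c(geom$centerRadius, geom$plateRadius))
  angles <- c(0, 2 * pi / 3, 4 * pi / 3)
  mkframe <- function(shift) {
    poses <- t(vapply(angles, function(a) {
      pos <- geom$center + (midR) * c(cos(a), sin(a))
      tang <- a + pi / 2
      pos <- pos + shift * c(cos(tang), sin(tang))
      c(pos, tang, 0.3, 0, 0.5)
    }, numeric(6)))
    base <- wormspan:::basePlateImage(cfg, geom,
      data.frame(row = numeric(), col = numeric(), radius = numeric(),
                 intensity = numeric(), firstDay = integer()), c(0, 0, 0))
    renderPlateFrame(cfg, poses, base = base)
  }
  fr <- lapply(seq(0, 8, length.out = 8), mkframe)
  seq <- FrameSequence(fr)
  pcfg <- simPipelineConfig(cfg)
  cm <- classifyPixels(stackSignatures(seq, pcfg@segmentation),
                       pcfg@segmentation)
  z <- detectZones(cm)
  cm <- recodeDarkByZone(cm, z)
  br <- dilateWallMotion(cm, z, pcfg@track)
  tracks <- labelPixelTracks(cm, z, br)
  expect_equal(sum(vapply(tracks, zoneClass, "") == "WALL"), 3)
})
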