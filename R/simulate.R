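## Ground-truthed synthetic plate simulator: backlit plate geometry with a
## dark-ringed wall shadow, worms as undulating tubes whose speed decays
## with age, a death schedule, hiding and dirt processes, and per-day
## rigid plate displacement. Every random choice derives from one seed, so
## image stacks and ground truth are bit-identical across runs.

#' Simulation configuration
#'
#' Defaults emulate a 55 mm plate imaged at quarter resolution (486 x 486;
#' native frames are 1944 x 1944) with 10 worms, 30 frames at 1 fps per
#' day, background grey near 48, a wall shadow covering 7% of the plate
#' area, worm bodies darker than grey 20, and an N2-like lifespan
#' distribution with mean 14 days. Worm geometry is given in fixture
#' pixels: at strong downscaling a worm's width is near the 1-pixel
#' rasterisation floor, so the rendered geometry (not a scaled native area
#' band) defines the matched worm model, see [simWormModel()].
#'
#' @slot imageSize square frame side in pixels.
#' @slot scale resolution factor relative to native 1944 x 1944.
#' @slot nWorms,nPlates,nDays,nFramesPerDay assay dimensions.
#' @slot backgroundLevel,noiseSd backlit background grey and Gaussian
#'   sensor noise.
#' @slot outsideIntensity,ringIntensity grey levels outside the plate and
#'   of the wall shadow rings.
#' @slot flickerFraction,flickerFlipNoise,flickerIntensity the noisy wall
#'   ring: fraction of the illuminated wall band that flickers, the
#'   probability that a flicker pixel deviates from its alternating
#'   dark/bright pattern in a frame, and its dark grey level. Flicker is
#'   near-alternating: condensation and sensor noise switch at a much
#'   higher frequency than anything a crawling worm produces.
#' @slot wallAreaFraction wall shadow area as a fraction of plate area.
#' @slot plateRadiusFraction plate radius as a fraction of the frame side.
#' @slot wormLength,wormWidth,wormIntensity,wormWaves,wormAmp worm tube
#'   geometry (pixels) and body grey level.
#' @slot maxStepPerFrame,minStepPerFrame,speedDecayPower per-frame
#'   displacement at age 0, its floor, and the age-decay exponent.
#' @slot headOnlyDays days before death during which only the head moves.
#' @slot interdayJumpNearDeath between-day displacement (px) of
#'   head-only-stage worms.
#' @slot lifespanMean,lifespanSd discretised Gaussian lifespan (days).
#' @slot hidingProb per worm-day probability of hiding in the wall shadow.
#' @slot dirtRate expected new dirt blobs per plate per day.
#' @slot dirtIntensityRange,dirtRadiusRange dirt blob parameters.
#' @slot displacementSd,rotationSd per-day plate placement error (px,
#'   degrees).
#' @slot confineHomeRanges keep worms in disjoint home cells (guarantees
#'   no aggregation; used by the artifact-free configuration).
#' @slot seed default RNG seed.
#' @export
setClass("SimConfig",
  representation(imageSize = "integer", scale = "numeric",
    nWorms = "integer", nPlates = "integer", nDays = "integer",
    nFramesPerDay = "integer", backgroundLevel = "numeric",
    noiseSd = "numeric", outsideIntensity = "numeric",
    ringIntensity = "numeric", flickerFraction = "numeric",
    flickerFlipNoise = "numeric", flickerIntensity = "numeric",
    wallAreaFraction = "numeric", plateRadiusFraction = "numeric",
    wormLength = "numeric", wormWidth = "numeric", wormIntensity = "numeric",
    wormWaves = "numeric", wormAmp = "numeric", maxStepPerFrame = "numeric",
    minStepPerFrame = "numeric", speedDecayPower = "numeric",
    headOnlyDays = "integer", interdayJumpNearDeath = "numeric",
    lifespanMean = "numeric", lifespanSd = "numeric", hidingProb = "numeric",
    dirtRate = "numeric", dirtIntensityRange = "numeric",
    dirtRadiusRange = "numeric", displacementSd = "numeric",
    rotationSd = "numeric", confineHomeRanges = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@hidingProb < 0 || object@hidingProb > 1 ||
      object@flickerFlipNoise < 0 || object@flickerFlipNoise > 1 ||
      object@flickerFraction < 0 || object@flickerFraction > 1)
    return("probabilities must be in [0, 1]")
  if (object@plateRadiusFraction >= 0.5)
    return("plate must fit inside the frame")
  if (object@wormIntensity >= 20)
    return("worm intensity must stay below grey level 20")
  TRUE
})

#' @rdname SimConfig-class
#' @param imageSize,scale,nWorms,nPlates,nDays,nFramesPerDay see slots.
#' @param backgroundLevel,noiseSd,outsideIntensity,ringIntensity see slots.
#' @param flickerFraction,flickerFlipNoise,flickerIntensity see slots.
#' @param wallAreaFraction,plateRadiusFraction see slots.
#' @param wormLength,wormWidth,wormIntensity,wormWaves,wormAmp see slots.
#' @param maxStepPerFrame,minStepPerFrame,speedDecayPower see slots.
#' @param headOnlyDays,interdayJumpNearDeath,lifespanMean,lifespanSd see slots.
#' @param hidingProb,dirtRate,dirtIntensityRange,dirtRadiusRange see slots.
#' @param displacementSd,rotationSd,confineHomeRanges,seed see slots.
#' @export
SimConfig <- function(imageSize = 486, scale = 0.25, nWorms = 10,
                      nPlates = 20, nDays = 30, nFramesPerDay = 30,
                      backgroundLevel = 48, noiseSd = 1.5,
                      outsideIntensity = 12, ringIntensity = 20,
                      flickerFraction = 0.35, flickerFlipNoise = 0.15,
                      flickerIntensity = 22, wallAreaFraction = 0.07,
                      plateRadiusFraction = 0.475, wormLength = 21,
                      wormWidth = 2.2, wormIntensity = 12, wormWaves = 1.3,
                      wormAmp = 2.0, maxStepPerFrame = 2.5,
                      minStepPerFrame = 0.3, speedDecayPower = 2,
                      headOnlyDays = 2, interdayJumpNearDeath = 6,
                      lifespanMean = 14, lifespanSd = 3, hidingProb = 0.03,
                      dirtRate = 0.3, dirtIntensityRange = c(15, 40),
                      dirtRadiusRange = c(1.8, 3), displacementSd = 4,
                      rotationSd = 0.5, confineHomeRanges = FALSE,
                      seed = 1L) {
  new("SimConfig", imageSize = as.integer(imageSize), scale = scale,
      nWorms = as.integer(nWorms), nPlates = as.integer(nPlates),
      nDays = as.integer(nDays), nFramesPerDay = as.integer(nFramesPerDay),
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      outsideIntensity = outsideIntensity, ringIntensity = ringIntensity,
      flickerFraction = flickerFraction, flickerFlipNoise = flickerFlipNoise,
      flickerIntensity = flickerIntensity,
      wallAreaFraction = wallAreaFraction,
      plateRadiusFraction = plateRadiusFraction, wormLength = wormLength,
      wormWidth = wormWidth, wormIntensity = wormIntensity,
      wormWaves = wormWaves, wormAmp = wormAmp,
      maxStepPerFrame = maxStepPerFrame, minStepPerFrame = minStepPerFrame,
      speedDecayPower = speedDecayPower,
      headOnlyDays = as.integer(headOnlyDays),
      interdayJumpNearDeath = interdayJumpNearDeath,
      lifespanMean = lifespanMean, lifespanSd = lifespanSd,
      hidingProb = hidingProb, dirtRate = dirtRate,
      dirtIntensityRange = dirtIntensityRange,
      dirtRadiusRange = dirtRadiusRange, displacementSd = displacementSd,
      rotationSd = rotationSd, confineHomeRanges = confineHomeRanges,
      seed = as.integer(seed))
}

#' Artifact-free simulation configuration
#'
#' No dirt, no hiding, no plate displacement, no flickering wall pixels,
#' and worms confined to disjoint home ranges so no aggregation can occur.
#' Under these conditions every live worm is unambiguously observable and
#' the automated curve should reproduce the ground truth exactly.
#'
#' @param nPlates,nWorms,nDays,seed assay dimensions.
#' @param ... further arguments to [SimConfig()].
#' @return A [SimConfig-class].
#' @export
cleanSimConfig <- function(nPlates = 5, nWorms = 10, nDays = 20, seed = 1L,
                           ...) {
  SimConfig(nPlates = nPlates, nWorms = nWorms, nDays = nDays,
            hidingProb = 0, dirtRate = 0, displacementSd = 0,
            rotationSd = 0, flickerFraction = 0, confineHomeRanges = TRUE,
            seed = seed, ...)
}

## Plate geometry in pixel units (pre-displacement, centred in the frame).
plateGeometry <- function(cfg) {
  ctr <- (cfg@imageSize + 1) / 2
  Rp <- cfg@plateRadiusFraction * cfg@imageSize
  Rc <- Rp * sqrt(1 - cfg@wallAreaFraction)
  dark <- rbind(c(Rc, Rc + 2.5), c(Rc + 5, Rc + 7.5))
  dark[dark > Rp] <- Rp
  gap <- c(Rc + 2.5, Rc + 5)
  list(center = c(ctr, ctr), plateRadius = Rp, centerRadius = Rc,
       darkRings = dark, gapRing = gap)
}

#' Schedule worm death days
#'
#' Draws one integer death day per worm from a discretised Gaussian
#' lifespan distribution (mean/sd from the configuration), floored at
#' headOnlyDays + 1 so that every worm has at least one fully mobile
#' imaging day. The death day is the first assay day on which the worm no
#' longer moves.
#'
#' @param cfg a [SimConfig-class].
#' @param seed RNG seed.
#' @param n number of worms (defaults to nWorms x nPlates).
#' @return Integer matrix nPlates x nWorms of death days.
#' @export
scheduleDeaths <- function(cfg, seed = cfg@seed, n = cfg@nPlates * cfg@nWorms) {
  withSeed(seed, {
    d <- round(stats::rnorm(n, cfg@lifespanMean, cfg@lifespanSd))
    d <- pmax(d, cfg@headOnlyDays + 1L)
    matrix(as.integer(d), cfg@nPlates, cfg@nWorms)
  })
}

## Sampled centreline of a worm pose (M x 2 matrix of row/col points).
## pose = c(r, c, phi, psi, headDefl, amp).
wormCenterline <- function(pose, cfg, M = 41L) {
  u <- seq(-0.5, 0.5, length.out = M)
  x <- u * cfg@wormLength
  y <- pose[6] * sin(2 * pi * cfg@wormWaves * u + pose[4])
  hd <- u > 0.25
  if (any(hd) && pose[5] != 0)
    y[hd] <- y[hd] + pose[5] * ((u[hd] - 0.25) / 0.25)^2
  co <- cos(pose[3]); si <- sin(pose[3])
  cbind(pose[1] + x * co - y * si, pose[2] + x * si + y * co)
}

## Stamp a worm tube onto an image (min-combine); returns the image, and
## optionally the deterministic silhouette (pixels dark enough to
## segment). The tube edge is a 1-px anti-aliased ramp.
stampWorm <- function(img, pts, cfg, silhouette = NULL) {
  h <- nrow(img); w <- ncol(img)
  pad <- cfg@wormWidth / 2 + 2
  r1 <- max(1L, floor(min(pts[, 1]) - pad)); r2 <- min(h, ceiling(max(pts[, 1]) + pad))
  c1 <- max(1L, floor(min(pts[, 2]) - pad)); c2 <- min(w, ceiling(max(pts[, 2]) + pad))
  if (r1 > r2 || c1 > c2) return(list(img = img, silhouette = silhouette))
  rows <- r1:r2; cols <- c1:c2
  gr <- rep(rows, times = length(cols))
  gc <- rep(cols, each = length(rows))
  d2 <- outer(gr, pts[, 1], "-")^2 + outer(gc, pts[, 2], "-")^2
  dmin <- sqrt(.rowMins(d2))
  cov <- pmin(1, pmax(0, cfg@wormWidth / 2 + 0.5 - dmin))
  det <- cfg@wormIntensity + (cfg@backgroundLevel - cfg@wormIntensity) * (1 - cov)
  sub <- img[rows, cols]
  img[rows, cols] <- pmin(sub, matrix(det, length(rows)))
  if (!is.null(silhouette)) {
    dark <- det < 33
    sil <- silhouette[rows, cols]
    silhouette[rows, cols] <- sil | matrix(dark, length(rows))
  }
  list(img = img, silhouette = silhouette)
}

.rowMins <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

#' Simulate one worm-day of poses
#'
#' Generates the per-frame poses of a single worm for one imaging
#' sequence. Moving worms advance a smooth random-walk heading with a
#' per-frame step that decays with age; worms within headOnlyDays of death
#' keep their body frozen and oscillate only the head segment; dead worms
#' hold one pose exactly.
#'
#' @param start numeric pose c(r, c, phi, psi, headDefl, amp).
#' @param ageFrac age as a fraction of this worm's lifespan (0..1).
#' @param cfg a [SimConfig-class].
#' @param seed RNG seed for this worm-day.
#' @param state "moving", "headOnly" or "dead".
#' @param boundCenter,boundRadius circular region confining the walk.
#' @return Matrix nFramesPerDay x 6 of poses.
#' @export
simulateWormKinematics <- function(start, ageFrac, cfg, seed,
                                   state = "moving",
                                   boundCenter = NULL, boundRadius = NULL) {
  T <- cfg@nFramesPerDay
  poses <- matrix(rep(start, each = T), T, 6)
  if (state == "dead") return(poses)
  withSeed(seed, {
    if (state == "headOnly") {
      phase <- stats::runif(1, 0, 2 * pi)
      poses[, 5] <- 2.2 * sin(0.7 * seq_len(T) + phase)
      return(poses)
    }
    step <- cfg@minStepPerFrame +
      (cfg@maxStepPerFrame - cfg@minStepPerFrame) *
      max(0, 1 - ageFrac)^cfg@speedDecayPower
    p <- start
    for (t in seq_len(T)) {
      p[3] <- p[3] + stats::rnorm(1, 0, 0.25)
      p[1] <- p[1] + step * cos(p[3])
      p[2] <- p[2] + step * sin(p[3])
      if (!is.null(boundCenter)) {
        d <- sqrt(sum((p[1:2] - boundCenter)^2))
        if (d + cfg@wormLength / 2 > boundRadius) {
          ## steer back towards the cell centre; step direction is
          ## (cos phi, sin phi) in (row, col)
          p[3] <- atan2(boundCenter[2] - p[2], boundCenter[1] - p[1]) +
            stats::rnorm(1, 0, 0.3)
        }
      }
      p[4] <- p[4] + 0.5
      poses[t, ] <- p
    }
    poses
  })
}

## ---- SimulatedAssay ----------------------------------------------------

#' Simulated lifespan assay with ground truth
#'
#' Produced by [simulateAssay()]. Holds the full death schedule, per-frame
#' worm poses, hiding events, dirt inventory, per-day plate displacement
#' and true live counts; frame sequences are rendered on demand with
#' [frameSequence()] so that arbitrarily long assays fit in memory.
#'
#' @slot config the [SimConfig-class] used.
#' @slot seed master seed.
#' @slot deathDays integer matrix nPlates x nWorms.
#' @slot poses nested list poses[[plate]][[day+1]]: array T x 6 x nWorms.
#' @slot hidden logical array nPlates x nDays x nWorms.
#' @slot dirt list per plate: data.frame row, col, radius, intensity,
#'   firstDay.
#' @slot transforms numeric array nPlates x nDays x 3 (angle, tx, ty).
#' @slot trueCounts integer matrix nPlates x nDays.
#' @slot wobble numeric matrix nPlates x 12: per-plate static plate
#'   texture (ring wobble amplitudes/phases, glint-gap phases, lawn
#'   boundary phases).
#' @slot plateIds character.
#' @slot days integer vector (0-based assay days).
#' @export
setClass("SimulatedAssay",
  representation(config = "SimConfig", seed = "integer",
                 deathDays = "matrix", poses = "list", hidden = "array",
                 dirt = "list", transforms = "array", trueCounts = "matrix",
                 wobble = "matrix", plateIds = "character",
                 days = "integer"))

setMethod("show", "SimulatedAssay", function(object) {
  cat(sprintf(
    "SimulatedAssay: %d plates x %d worms x %d days (%d frames/day, %d px)\n",
    object@config@nPlates, object@config@nWorms, object@config@nDays,
    object@config@nFramesPerDay, object@config@imageSize))
})

#' Simulate a full lifespan assay
#'
#' Draws the death schedule, simulates every worm's kinematics for every
#' plate-day (including the head-only end-of-life stage, frozen death
#' poses, hiding events and between-day movements), accrues dirt, and
#' draws per-day rigid plate placement errors. Frames are not rendered
#' here; use [frameSequence()].
#'
#' @param cfg a [SimConfig-class].
#' @param seed master seed (default from cfg).
#' @return A [SimulatedAssay-class].
#' @export
simulateAssay <- function(cfg = SimConfig(), seed = cfg@seed) {
  seed <- as.integer(seed)
  geom <- plateGeometry(cfg)
  nP <- cfg@nPlates; nW <- cfg@nWorms; nD <- cfg@nDays
  deathDays <- scheduleDeaths(cfg, subSeed(seed, 1L))
  hidden <- array(FALSE, c(nP, nD, nW))
  transforms <- array(0, c(nP, nD, 3))
  trueCounts <- matrix(0L, nP, nD)
  poses <- vector("list", nP)
  dirt <- vector("list", nP)
  roamRadius <- geom$centerRadius - cfg@wormLength / 2 - 6
  wobble <- matrix(0, nP, 12)
  withSeed(subSeed(seed, 2L), {
    for (p in seq_len(nP)) {
      wobble[p, ] <- c(stats::runif(3, 0.5, 1.2), stats::runif(9, 0, 2 * pi))
      ## home ranges: disjoint cells on a ring, or the whole centre disc
      if (cfg@confineHomeRanges) {
        ringR <- 0.55 * geom$centerRadius
        ang <- 2 * pi * (seq_len(nW) - 1) / nW
        cellR <- min(0.75 * pi * ringR / nW, roamRadius - ringR)
        cells <- lapply(seq_len(nW), function(i)
          list(center = geom$center + ringR * c(cos(ang[i]), sin(ang[i])),
               radius = max(cellR, cfg@wormLength / 2 + 4)))
      } else {
        cells <- rep(list(list(center = geom$center, radius = roamRadius)),
                     nW)
      }
      ## initial poses; in free-roaming mode worms start dispersed (the
      ## emulated strains do not aggregate: overlaps are transient path
      ## crossings, not resting clusters)
      minSpace <- 1.5 * cfg@wormLength
      placeApart <- function(i, others) {
        best <- NULL; bestD <- -Inf
        for (try in 1:20) {
          off <- stats::runif(2, -1, 1) * cells[[i]]$radius * 0.6
          cand <- cells[[i]]$center + off
          d <- if (length(others)) min(sqrt(colSums((t(others) - cand)^2)))
               else Inf
          if (d > bestD) { bestD <- d; best <- cand }
          if (d >= minSpace) break
        }
        best
      }
      cur <- matrix(0, nW, 6)
      for (i in seq_len(nW)) {
        others <- if (i > 1L && !cfg@confineHomeRanges)
          cur[seq_len(i - 1L), 1:2, drop = FALSE] else NULL
        cur[i, ] <- c(placeApart(i, others), stats::runif(1, 0, 2 * pi),
                      stats::runif(1, 0, 2 * pi), 0,
                      cfg@wormAmp * stats::runif(1, 0.7, 1.2))
      }
      platePoses <- vector("list", nD)
      for (d in seq_len(nD)) {
        day <- d - 1L
        dayPoses <- array(0, c(cfg@nFramesPerDay, 6, nW))
        for (wi in seq_len(nW)) {
          D <- deathDays[p, wi]
          state <- if (day >= D) "dead"
            else if (day >= D - cfg@headOnlyDays) "headOnly" else "moving"
          if (state == "moving" && cfg@hidingProb > 0 &&
              stats::runif(1) < cfg@hidingProb)
            hidden[p, d, wi] <- TRUE
          kin <- simulateWormKinematics(
            cur[wi, ], ageFrac = min(1, day / D), cfg,
            seed = subSeed(seed, 3L, p, d, wi), state = state,
            boundCenter = cells[[wi]]$center,
            boundRadius = cells[[wi]]$radius)
          dayPoses[, , wi] <- kin
          ## end-of-day pose becomes tomorrow's start (plus between-day
          ## movement for live worms)
          end <- kin[cfg@nFramesPerDay, ]
          if (state == "moving") {
            nxt <- end
            cand <- NULL; bestD <- -Inf
            for (try in 1:20) {
              jump <- stats::runif(1, 0.3, 1) * cells[[wi]]$radius
              dir <- stats::runif(1, 0, 2 * pi)
              cc <- end[1:2] + jump * c(cos(dir), sin(dir))
              dc <- sqrt(sum((cc - cells[[wi]]$center)^2))
              if (dc > cells[[wi]]$radius - cfg@wormLength / 2)
                cc <- cells[[wi]]$center +
                  (cc - cells[[wi]]$center) *
                  (cells[[wi]]$radius - cfg@wormLength / 2) / max(dc, 1e-9) * 0.8
              dmin <- if (!cfg@confineHomeRanges && nW > 1L)
                min(sqrt(colSums((t(cur[-wi, 1:2, drop = FALSE]) - cc)^2)))
                else Inf
              if (dmin > bestD) { bestD <- dmin; cand <- cc }
              if (dmin >= minSpace) break
            }
            nxt[1:2] <- cand
            nxt[3] <- stats::runif(1, 0, 2 * pi)
            nxt[4] <- stats::runif(1, 0, 2 * pi)
            nxt[5] <- 0
            ## tomorrow may begin the head-only stage: re-curl slightly
            nxt[6] <- cfg@wormAmp * stats::runif(1, 0.7, 1.2)
            if (day + 1L >= D) nxt <- end   # dies tonight: freeze in place
            cur[wi, ] <- nxt
          } else if (state == "headOnly") {
            nxt <- end
            dir <- stats::runif(1, 0, 2 * pi)
            nxt[1:2] <- end[1:2] +
              cfg@interdayJumpNearDeath * c(cos(dir), sin(dir))
            dc <- sqrt(sum((nxt[1:2] - cells[[wi]]$center)^2))
            if (dc > cells[[wi]]$radius)
              nxt[1:2] <- end[1:2]
            nxt[4] <- stats::runif(1, 0, 2 * pi)
            nxt[6] <- end[6] * stats::runif(1, 0.85, 1.15)
            if (day + 1L >= D) nxt <- end   # freeze exactly at death
            cur[wi, ] <- nxt
          } # dead: cur stays frozen
        }
        platePoses[[d]] <- dayPoses
        trueCounts[p, d] <- sum(deathDays[p, ] > day)
        if (day > 0L) {
          transforms[p, d, 1] <- max(-3, min(3, stats::rnorm(1, 0, cfg@rotationSd)))
          transforms[p, d, 2:3] <- pmax(-12, pmin(12,
            stats::rnorm(2, 0, cfg@displacementSd)))
        }
      }
      poses[[p]] <- platePoses
      ## dirt accrual over days, within the plate centre
      nNew <- stats::rpois(nD, cfg@dirtRate)
      total <- sum(nNew)
      if (total > 0) {
        ang <- stats::runif(total, 0, 2 * pi)
        rad <- sqrt(stats::runif(total)) * (geom$centerRadius - 8)
        dirt[[p]] <- data.frame(
          row = geom$center[1] + rad * cos(ang),
          col = geom$center[2] + rad * sin(ang),
          radius = stats::runif(total, cfg@dirtRadiusRange[1],
                                cfg@dirtRadiusRange[2]),
          intensity = stats::runif(total, cfg@dirtIntensityRange[1],
                                   cfg@dirtIntensityRange[2]),
          firstDay = rep(seq_len(nD) - 1L, nNew))
      } else {
        dirt[[p]] <- data.frame(row = numeric(), col = numeric(),
                                radius = numeric(), intensity = numeric(),
                                firstDay = integer())
      }
    }
  })
  new("SimulatedAssay", config = cfg, seed = seed, deathDays = deathDays,
      poses = poses, hidden = hidden, dirt = dirt, transforms = transforms,
      trueCounts = trueCounts, wobble = wobble,
      plateIds = sprintf("p%02d", seq_len(nP)),
      days = seq_len(nD) - 1L)
}

## ---- rendering ---------------------------------------------------------

## Static plate image for one plate-day (no noise, no worms, no flicker):
## background, outside-plate dark, bacterial lawn, wall rings, dirt
## existing by that day. The day transform shifts circles by its
## translation (rotation about the frame centre leaves concentric circles
## unchanged) and rotates dirt and all angular texture. `wobble` is a
## 12-parameter per-plate static texture: ring-radius irregularity
## (3 amplitudes + 3 phases, modes 3/8/15), angular glint-gap phases for
## the outer ring (3, modes 9/17/26) and lawn-boundary phases (3, modes
## 2/3/5). Real refraction rings are broken and irregular and the E. coli
## lawn edge is visible; besides realism, this texture is what makes the
## plate rotationally asymmetric enough for inter-day alignment.
basePlateImage <- function(cfg, geom, dirtDf, transform,
                           wobble = rep(0, 12)) {
  n <- cfg@imageSize
  img <- matrix(cfg@backgroundLevel, n, n)
  ctr <- geom$center + transform[2:3]
  rows <- seq_len(n) - ctr[1]; cols <- seq_len(n) - ctr[2]
  rr <- sqrt(outer(rows^2, cols^2, "+"))
  textured <- any(wobble != 0)
  if (textured) {
    rmat <- matrix(rows, n, n)
    cmat <- matrix(cols, n, n, byrow = TRUE)
    beta <- atan2(cmat, rmat) - transform[1] * pi / 180
    rr <- rr - (wobble[1] * sin(3 * beta + wobble[4]) +
                wobble[2] * sin(8 * beta + wobble[5]) +
                wobble[3] * sin(15 * beta + wobble[6]))
    ## lawn: a slightly darker irregular disc in the plate centre (well
    ## above the segmentation threshold; invisible to the pipeline)
    lawnR <- 0.45 * geom$centerRadius +
      3 * sin(2 * beta + wobble[10]) + 2 * sin(3 * beta + wobble[11]) +
      2 * sin(5 * beta + wobble[12])
    img[rr < lawnR] <- cfg@backgroundLevel - 5
  }
  img[rr > geom$plateRadius] <- cfg@outsideIntensity
  for (k in seq_len(nrow(geom$darkRings))) {
    band <- rr >= geom$darkRings[k, 1] & rr <= geom$darkRings[k, 2]
    if (textured && k > 1L) {
      ## outer rings are broken by bright refraction glints
      prof <- sin(9 * beta + wobble[7]) + sin(17 * beta + wobble[8]) +
        sin(26 * beta + wobble[9])
      band <- band & prof < 1.7
    }
    img[band] <- cfg@ringIntensity
  }
  if (nrow(dirtDf) > 0) {
    tf <- RigidTransform(transform[1], transform[2], transform[3])
    pts <- transformPoints(cbind(dirtDf$row, dirtDf$col), tf, c(n, n))
    for (k in seq_len(nrow(dirtDf))) {
      rad <- dirtDf$radius[k]
      r0 <- pts[k, 1]; c0 <- pts[k, 2]
      rs <- max(1, floor(r0 - rad)):min(n, ceiling(r0 + rad))
      cs <- max(1, floor(c0 - rad)):min(n, ceiling(c0 + rad))
      d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
      sub <- img[rs, cs]
      sub[d2 <= rad^2] <- pmin(sub[d2 <= rad^2], dirtDf$intensity[k])
      img[rs, cs] <- sub
    }
  }
  img
}

#' Render one simulated frame
#'
#' Draws the plate background, wall rings, dirt, flicker and worm tubes
#' for one frame. Mostly used through [frameSequence()]; exposed for
#' constructing bespoke scenes in tests.
#'
#' @param cfg a [SimConfig-class].
#' @param wormPoses nWorms x 6 matrix of poses (may have zero rows).
#' @param base optional precomputed static image (from internal
#'   rendering); default builds one without dirt and identity transform.
#' @param transform numeric (angle, tx, ty) applied to worm positions.
#' @param flickerIdx,flickerDark linear indices of designated flicker
#'   pixels and their dark state for this frame.
#' @param noise matrix of sensor noise to add (or NULL).
#' @param silhouette logical: also return the deterministic worm
#'   silhouette mask.
#' @return The frame matrix, or list(img, silhouette).
#' @export
renderPlateFrame <- function(cfg, wormPoses, base = NULL,
                             transform = c(0, 0, 0), flickerIdx = integer(),
                             flickerDark = logical(), noise = NULL,
                             silhouette = FALSE) {
  geom <- plateGeometry(cfg)
  if (is.null(base))
    base <- basePlateImage(cfg, geom, data.frame(row = numeric(),
      col = numeric(), radius = numeric(), intensity = numeric(),
      firstDay = integer()), transform)
  img <- base
  if (!is.null(noise)) img <- img + noise
  if (length(flickerIdx))
    img[flickerIdx[flickerDark]] <- cfg@flickerIntensity
  sil <- if (silhouette) matrix(FALSE, nrow(img), ncol(img)) else NULL
  n <- cfg@imageSize
  tf <- RigidTransform(transform[1], transform[2], transform[3])
  if (length(wormPoses) && nrow(wormPoses) > 0) {
    for (wi in seq_len(nrow(wormPoses))) {
      pose <- wormPoses[wi, ]
      pts <- wormCenterline(pose, cfg)
      if (any(transform != 0)) pts <- transformPoints(pts, tf, c(n, n))
      st <- stampWorm(img, pts, cfg, sil)
      img <- st$img
      sil <- st$silhouette
    }
  }
  img <- pmin(pmax(img, 0), 255)
  if (silhouette) list(img = img, silhouette = sil) else img
}

#' Render the frame sequence of one simulated plate-day
#'
#' @param assay a [SimulatedAssay-class].
#' @param plate plate index (1-based) or plate id.
#' @param day assay day (0-based, as in \code{assay@days}).
#' @param withTruth also return per-frame worm silhouette masks.
#' @return A [FrameSequence-class], or list(seq, silhouettes) when
#'   \code{withTruth}.
#' @export
frameSequence <- function(assay, plate, day, withTruth = FALSE) {
  cfg <- assay@config
  if (is.character(plate)) plate <- match(plate, assay@plateIds)
  d <- match(day, assay@days)
  geom <- plateGeometry(cfg)
  dirtDf <- assay@dirt[[plate]]
  dirtDf <- dirtDf[dirtDf$firstDay <= day, , drop = FALSE]
  tfv <- assay@transforms[plate, d, ]
  base <- basePlateImage(cfg, geom, dirtDf, tfv, wobble = assay@wobble[plate, ])
  n <- cfg@imageSize
  T <- cfg@nFramesPerDay
  ## flicker set: designated pixels in the illuminated wall band
  flickerIdx <- integer()
  flickerStates <- NULL
  if (cfg@flickerFraction > 0) {
    fl <- withSeed(subSeed(assay@seed, 4L, plate, d), {
      ctr <- geom$center + tfv[2:3]
      rr <- sqrt(outer((seq_len(n) - ctr[1])^2,
                       (seq_len(n) - ctr[2])^2, "+"))
      band <- which(rr >= geom$gapRing[1] & rr <= geom$gapRing[2])
      idx <- band[stats::runif(length(band)) < cfg@flickerFraction]
      phase <- sample(0:1, length(idx), replace = TRUE)
      alt <- outer(phase, seq_len(T), function(p, t) (p + t) %% 2L == 0L)
      err <- matrix(stats::runif(length(idx) * T) < cfg@flickerFlipNoise,
                    length(idx), T)
      list(idx = idx, states = xor(alt, err))
    })
    flickerIdx <- fl$idx
    flickerStates <- fl$states
  }
  framesArr <- array(0, c(n, n, T))
  sils <- if (withTruth) vector("list", T) else NULL
  poseArr <- assay@poses[[plate]][[d]]
  hiddenW <- assay@hidden[plate, d, ]
  drawW <- which(!hiddenW)
  for (t in seq_len(T)) {
    noise <- withSeed(subSeed(assay@seed, 5L, plate, d, t), {
      if (cfg@noiseSd > 0) matrix(stats::rnorm(n * n, 0, cfg@noiseSd), n, n)
      else NULL
    })
    wp <- t(matrix(poseArr[t, , drawW], nrow = 6))
    out <- renderPlateFrame(cfg, wp, base = base, transform = tfv,
                            flickerIdx = flickerIdx,
                            flickerDark = if (length(flickerIdx))
                              flickerStates[, t] else logical(),
                            noise = noise, silhouette = withTruth)
    if (withTruth) {
      framesArr[, , t] <- out$img
      sils[[t]] <- out$silhouette
    } else framesArr[, , t] <- out
  }
  seq <- FrameSequence(framesArr, plateId = assay@plateIds[plate],
                       day = day)
  if (withTruth) list(seq = seq, silhouettes = sils) else seq
}

#' Render a two-worm crossing scene
#'
#' Draws two model-conforming worms whose body midsections are steered
#' through a shared waypoint at a transversal angle, the way a real
#' two-worm collision event looks in a frame; scenes where the bodies
#' overlap beyond one localized crossing (or whose silhouettes do not
#' merge into a single blob) are rejected. Used to exercise the
#' disaggregation optimiser against known ground truth.
#'
#' @param cfg a [SimConfig-class] (worm geometry and photometry).
#' @param n side of the rendered crop in pixels.
#' @return A merged two-worm [WormBlob-class], or NULL if the sampled
#'   scene was rejected.
#' @export
renderCrossingScene <- function(cfg, n = 80L) {
  tmp <- cfg
  tmp@imageSize <- as.integer(n)
  crossAt <- c(n / 2, n / 2)
  mk <- function(phi) {
    pose <- c(0, 0, phi, stats::runif(1, 0, 2 * pi), 0,
              cfg@wormAmp * stats::runif(1, 0.7, 1.2))
    pts <- wormCenterline(pose, tmp)
    u <- stats::runif(1, 0.3, 0.7)
    at <- pts[round(1 + u * (nrow(pts) - 1)), ]
    pose[1:2] <- crossAt - at
    pose
  }
  phi1 <- stats::runif(1, 0, pi)
  p1 <- mk(phi1)
  p2 <- mk(phi1 + sample(c(-1, 1), 1) * stats::runif(1, 0.7, 2.4))
  pts1 <- wormCenterline(p1, tmp)
  pts2 <- wormCenterline(p2, tmp)
  d2 <- outer(pts1[, 1], pts2[, 1], "-")^2 +
    outer(pts1[, 2], pts2[, 2], "-")^2
  near <- which(d2 < (1.5 * cfg@wormWidth)^2, arr.ind = TRUE)
  if (nrow(near) == 0L) return(NULL)
  M <- nrow(pts1)
  if (diff(range(near[, 1])) > 0.25 * M ||
      diff(range(near[, 2])) > 0.25 * M) return(NULL)
  out <- renderPlateFrame(tmp, rbind(p1, p2),
                          base = matrix(cfg@backgroundLevel, n, n),
                          silhouette = TRUE)
  lab <- label8(out$silhouette)
  if (max(lab) != 1L) return(NULL)
  px <- which(lab == 1L)
  rc <- idxToRowCol(px, c(n, n))
  new("WormBlob", pixels = as.integer(px), dim = c(as.integer(n),
      as.integer(n)), area = length(px),
      centroid = c(mean(rc[, 1]), mean(rc[, 2])),
      meanIntensity = mean(out$img[px]), frameIndex = 1L)
}

#' Matched worm model for a simulation configuration
#'
#' Renders one canonical worm at the configured geometry, measures its
#' segmented area and skeleton length/width, and derives a worm model
#' whose theoretical shape and area band match the rendered geometry. At
#' reduced fixture resolution a worm's drawn width sits near the 1-pixel
#' rasterisation floor, so measuring the renderer (rather than scaling the
#' native-area band by scale squared) is what keeps the model and the
#' images consistent.
#'
#' @param cfg a [SimConfig-class].
#' @return A [WormModel-class].
#' @export
simWormModel <- function(cfg) {
  n <- as.integer(4 * ceiling(cfg@wormLength))
  tmp <- cfg
  tmp@imageSize <- n
  pose <- c((n + 1) / 2, (n + 1) / 2, 0.3, 0.2, 0, cfg@wormAmp)
  img <- matrix(cfg@backgroundLevel, n, n)
  st <- stampWorm(img, wormCenterline(pose, tmp), tmp,
                  matrix(FALSE, n, n))
  sil <- st$silhouette
  area <- sum(sil)
  blob <- new("WormBlob", pixels = as.integer(which(sil)), dim = c(n, n),
              area = area, centroid = c(0, 0), meanIntensity = 10,
              frameIndex = 1L)
  g <- buildSkeletonGraph(blob)
  L <- sum(vapply(g@edges, function(e) e$length, 1))
  W <- if (length(g@edges)) mean(vapply(g@edges, function(e) e$width, 1))
       else cfg@wormWidth
  new("WormModel", theoreticalLength = L, theoreticalWidth = W,
      minArea = max(3, 0.4 * area), maxArea = 2.6 * area,
      maxWormIntensity = 20, aggregateMinArea = 1.45 * area,
      maxSkeletonEdges = 12L)
}

#' Pipeline configuration matched to a simulation
#'
#' Standard pipeline parameters at the simulation's scale, with the worm
#' model derived from the rendered worm geometry ([simWormModel()]) and
#' the filter dividing day set to the configured mean lifespan.
#'
#' @param cfg a [SimConfig-class].
#' @return A [PipelineConfig-class].
#' @export
simPipelineConfig <- function(cfg) {
  PipelineConfig(scale = cfg@scale,
                 wormModel = simWormModel(cfg),
                 filter = FilterConfig(dividingDay = cfg@lifespanMean))
}

#' Ground-truth lifespan curves of a simulated assay
#'
#' @param assay a [SimulatedAssay-class].
#' @return Named list of [LifespanCurve-class], one per plate.
#' @export
trueCurves <- function(assay) {
  out <- lapply(seq_len(assay@config@nPlates), function(p)
    LifespanCurve(assay@plateIds[p], assay@config@nWorms, assay@days,
                  assay@trueCounts[p, ]))
  stats::setNames(out, assay@plateIds)
}
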