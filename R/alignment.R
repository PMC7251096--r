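## Pipeline step 7: inter-day rigid alignment and death-event detection
## for quiescent worms.

## Integer-peak translation between two images via FFT cross-correlation,
## refined to sub-pixel by a parabolic fit around the peak.
fftTranslation <- function(ref, tgt, maxShift) {
  a <- ref - mean(ref)
  b <- tgt - mean(tgt)
  h <- nrow(a); w <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  ## cc[1 + dr mod h, 1 + dc mod w] ~ correlation of ref vs tgt shifted by
  ## (dr, dc); restrict the search to |shift| <= maxShift
  dr <- c(0:(h - 1)); dr[dr > h / 2] <- dr[dr > h / 2] - h
  dc <- c(0:(w - 1)); dc[dc > w / 2] <- dc[dc > w / 2] - w
  ok <- outer(abs(dr) <= maxShift, abs(dc) <= maxShift, "&")
  cc[!ok] <- -Inf
  m <- arrayInd(which.max(cc), dim(cc))
  peakR <- m[1]; peakC <- m[2]
  sub <- function(vals) {
    ## parabolic 3-point refinement; vals = (left, centre, right)
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (!is.finite(den) || den == 0) return(0)
    max(min(0.5 * (vals[1] - vals[3]) / den, 0.5), -0.5)
  }
  rm1 <- (peakR - 2) %% h + 1; rp1 <- peakR %% h + 1
  cm1 <- (peakC - 2) %% w + 1; cp1 <- peakC %% w + 1
  offR <- sub(c(cc[rm1, peakC], cc[peakR, peakC], cc[rp1, peakC]))
  offC <- sub(c(cc[peakR, cm1], cc[peakR, peakC], cc[peakR, cp1]))
  c(dr[peakR] + offR, dc[peakC] + offC)
}

## Score a candidate rigid transform prev -> curr by correlating the
## warped previous frame with the current frame (interior crop to avoid
## border fill effects).
scoreTransform <- function(prev, curr, angle, tx, ty, margin) {
  warped <- warpRigid(prev, angle, tx, ty, fill = NA)
  h <- nrow(curr); w <- ncol(curr)
  rs <- (1 + margin):(h - margin); cs <- (1 + margin):(w - margin)
  a <- warped[rs, cs]; b <- curr[rs, cs]
  ok <- !is.na(a)
  if (sum(ok) < 100) return(-1)
  nccScore(a[ok], b[ok])
}

## The representative frame of a sequence: the temporally middle frame.
representativeFrame <- function(seq) {
  t <- ceiling(nFrames(seq) / 2)
  seq@frames[, , t]
}

#' Estimate the rigid transform between consecutive-day sequences
#'
#' Recovers the small rotation + translation that maps the previous day's
#' plate image onto the current day's (plates are repositioned by hand
#' between captures). Translation comes from FFT cross-correlation of the
#' representative frames with sub-pixel refinement; rotation from a
#' coarse-to-fine grid search on 2x-downsampled images, skipped when the
#' unrotated match is already near-perfect. Returns the identity if no
#' candidate beats the unaligned score.
#'
#' @param curr,prev [FrameSequence-class] objects of the same plate on
#'   consecutive days.
#' @param cfg a [MotionConfig-class] (search bounds).
#' @return A [RigidTransform-class] mapping prev coordinates onto curr.
#' @export
alignDays <- function(curr, prev, cfg = MotionConfig()) {
  a <- representativeFrame(prev)
  b <- representativeFrame(curr)
  if (!all(dim(a) == dim(b))) stop("day images have mismatched shapes")
  maxT <- cfg@maxAlignmentTranslation
  h <- nrow(b); w <- ncol(b)
  margin <- as.integer(ceiling(maxT)) + 4L
  ## sparse scoring support: the strongest-gradient pixels of the current
  ## image (ring edges, worms, dirt), away from the border
  gx <- abs(b - shiftMat(b, 1, 0, b[1, 1]))
  gy <- abs(b - shiftMat(b, 0, 1, b[1, 1]))
  g <- gx + gy
  g[c(seq_len(margin), h - seq_len(margin) + 1L), ] <- 0
  g[, c(seq_len(margin), w - seq_len(margin) + 1L)] <- 0
  nS <- min(15000L, sum(g > 0))
  S <- order(g, decreasing = TRUE)[seq_len(nS)]
  Src <- idxToRowCol(S, c(h, w))
  bS <- b[S]
  sparseScore <- function(angle, tx, ty) {
    inv <- invertTransform(RigidTransform(angle, tx, ty), c(h, w))
    src <- transformPoints(Src, inv, c(h, w))
    vals <- bilinearSample(a, src[, 1], src[, 2], fill = NA)
    ok <- !is.na(vals)
    if (sum(ok) < 500) return(-1)
    nccScore(vals[ok], bS[ok])
  }
  t0 <- fftTranslation(b, a, maxT)   # shift of prev within curr
  s0 <- sparseScore(0, t0[1], t0[2])
  base <- sparseScore(0, 0, 0)
  best <- list(angle = 0, tx = t0[1], ty = t0[2], score = s0)
  if (s0 < 0.995 && cfg@maxAlignmentRotation > 0) {
    ## alternate a sparse angle search (at the current translation) with a
    ## full-resolution FFT translation re-estimate (at the current angle);
    ## the grids shrink each round
    ang <- 0; tt <- t0
    grids <- list(seq(-cfg@maxAlignmentRotation, cfg@maxAlignmentRotation,
                      by = 0.5),
                  seq(-0.7, 0.7, by = 0.1), seq(-0.15, 0.15, by = 0.05))
    for (r in seq_along(grids)) {
      angles <- if (r == 1L) grids[[r]] else ang + grids[[r]]
      sc <- vapply(angles, function(g) sparseScore(g, tt[1], tt[2]), 1)
      ang <- angles[which.max(sc)]
      aw <- warpRigid(a, ang, 0, 0, fill = mean(a))
      tt <- fftTranslation(b, aw, maxT)
    }
    sc <- sparseScore(ang, tt[1], tt[2])
    if (sc > best$score)
      best <- list(angle = ang, tx = tt[1], ty = tt[2], score = sc)
  }
  if (best$score <= base)
    return(RigidTransform(0, 0, 0, score = base))
  RigidTransform(best$angle, best$tx, best$ty, score = best$score)
}

#' Inter-day death check for a quiescent worm
#'
#' Extracts the worm's segmented sub-image window from the current day and
#' the rigidly mapped window from the previous day's last frame, and
#' compares the binary masks with a normalized match score, maximised over
#' a small local translation. A score at or above the threshold means no
#' shape change in 24 h: the worm is dead. A lower score means the worm
#' moved or re-curled since yesterday (or was elsewhere entirely): it
#' counts as alive via the inter-day term.
#'
#' @param track a QUIESCENT [WormTrack-class] from the current sequence.
#' @param currFrame current-day frame used for the worm's window (the last
#'   frame of the sequence).
#' @param prevFrame previous-day frame (its last frame: the observation
#'   closest in time).
#' @param transform [RigidTransform-class] mapping prev onto curr.
#' @param cfg a [MotionConfig-class].
#' @param segcfg a [SegmentationConfig-class] for the sub-masks.
#' @return List with \code{alive} (logical), \code{score}, and
#'   \code{outOfImage} flag (window fell outside the previous image).
#' @export
detectInterdayMotion <- function(track, currFrame, prevFrame, transform,
                                 cfg = MotionConfig(),
                                 segcfg = SegmentationConfig()) {
  blob <- track@blobs[[length(track@blobs)]]
  rc <- idxToRowCol(blob@pixels, blob@dim)
  pad <- max(6L, as.integer(cfg@matchSearchRadius) + 4L)
  r1 <- max(1L, min(rc[, 1]) - pad); r2 <- min(blob@dim[1], max(rc[, 1]) + pad)
  c1 <- max(1L, min(rc[, 2]) - pad); c2 <- min(blob@dim[2], max(rc[, 2]) + pad)
  maskNow <- segmentFrame(currFrame[r1:r2, c1:c2, drop = FALSE], segcfg)
  ## previous-day window: map current window coordinates back through the
  ## inverse transform and sample the previous frame
  grid <- as.matrix(expand.grid(r = r1:r2, c = c1:c2))
  inv <- invertTransform(transform, dim(currFrame))
  src <- transformPoints(grid, inv, dim(currFrame))
  outOfImage <- any(src[, 1] < 1 | src[, 1] > nrow(prevFrame) |
                    src[, 2] < 1 | src[, 2] > ncol(prevFrame))
  vals <- bilinearSample(prevFrame, src[, 1], src[, 2],
                         fill = segcfg@backgroundLevel)
  prevWin <- matrix(vals, r2 - r1 + 1L, c2 - c1 + 1L)
  maskPrev <- segmentFrame(prevWin, segcfg)
  ## normalized cross-correlation of softened masks (a light Gaussian blur
  ## makes the score tolerant to the sub-pixel rasterisation differences a
  ## compensated plate displacement leaves behind), maximised over a small
  ## translation slack
  blur <- function(m) {
    if (nrow(m) < 7 || ncol(m) < 7) return(m + 0)
    matrix(EBImage::gblur(matrix(as.numeric(m), nrow(m)), sigma = 1.2),
           nrow(m))
  }
  bNow <- blur(maskNow)
  bPrev <- blur(maskPrev)
  rad <- as.integer(cfg@matchSearchRadius)
  score <- 0
  if (sum(maskNow) == 0 && sum(maskPrev) == 0) {
    score <- 1
  } else if (sum(maskNow) > 0 && sum(maskPrev) > 0) {
    for (dr in -rad:rad) for (dc in -rad:rad) {
      score <- max(score, nccScore(bNow, shiftMat(bPrev, dr, dc, 0)))
    }
  }
  list(alive = score < cfg@matchScoreThreshold, score = score,
       outOfImage = outOfImage)
}

## Inverse of a rigid transform on an image of dimensions dm.
invertTransform <- function(transform, dm) {
  th <- -transform@angle * pi / 180
  co <- cos(th); si <- sin(th)
  ## forward: p' = R(p - c) + c + t  =>  p = R^-1(p' - c - t) + c
  ## expressed as another centre-rotation transform:
  ## p = R^-1(p' - c) + c - R^-1 t
  tx <- -(co * transform@tx - si * transform@ty)
  ty <- -(si * transform@tx + co * transform@ty)
  RigidTransform(-transform@angle, tx, ty)
}
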