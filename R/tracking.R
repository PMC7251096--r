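## Pipeline step 5: worm-level tracking along the sequence by blob overlap
## and motion/quiescence classification.

## Pixel overlap of two blobs (counts of shared linear indices).
blobOverlap <- function(a, b) {
  length(intersect(a@pixels, b@pixels))
}

#' Track worms along a frame sequence
#'
#' Greedy frame-to-frame association by maximal pixel-set overlap: at 1 fps
#' worms move little, so consecutive detections of the same worm overlap.
#' Unmatched blobs start new tracks; each blob joins at most one track. A
#' track may skip a single frame (detection gap) and resume if overlap
#' returns.
#'
#' @param perFrameWorms list (one element per frame) of lists of
#'   [WormBlob-class].
#' @return List of [WormTrack-class] (motion state not yet set).
#' @export
trackWorms <- function(perFrameWorms) {
  tracks <- list()     # each: list(blobs=, frames=, lastBlob=, lastFrame=)
  for (t in seq_along(perFrameWorms)) {
    blobs <- perFrameWorms[[t]]
    if (length(blobs) == 0L) next
    ## candidate tracks: those last seen in frame t-1 or t-2 (1-frame gap)
    open <- which(vapply(tracks, function(tr) tr$lastFrame >= t - 2L, TRUE))
    taken <- logical(length(blobs))
    if (length(open) > 0L) {
      ov <- matrix(0L, length(open), length(blobs))
      for (i in seq_along(open))
        for (j in seq_along(blobs))
          ov[i, j] <- blobOverlap(tracks[[open[i]]]$lastBlob, blobs[[j]])
      while (TRUE) {
        m <- which.max(ov)
        if (length(m) == 0L || ov[m] == 0L) break
        i <- (m - 1L) %% nrow(ov) + 1L
        j <- (m - 1L) %/% nrow(ov) + 1L
        ti <- open[i]
        tracks[[ti]]$blobs <- c(tracks[[ti]]$blobs, blobs[j])
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, t)
        tracks[[ti]]$lastBlob <- blobs[[j]]
        tracks[[ti]]$lastFrame <- t
        taken[j] <- TRUE
        ov[i, ] <- 0L
        ov[, j] <- 0L
      }
    }
    for (j in which(!taken)) {
      tracks[[length(tracks) + 1L]] <- list(blobs = blobs[j], frames = t,
                                            lastBlob = blobs[[j]],
                                            lastFrame = t)
    }
  }
  lapply(tracks, function(tr)
    new("WormTrack", blobs = tr$blobs, frames = as.integer(tr$frames)))
}

#' Classify a worm track as in motion or quiescent
#'
#' A track is MOTION if the maximum pairwise centroid displacement across
#' its blobs reaches the configured minimum, or if the symmetric
#' difference between its first and last pixel footprints exceeds 20% of
#' the blob area (posture change without translation). Otherwise it is
#' QUIESCENT and deferred to the inter-day comparison.
#'
#' @param track a [WormTrack-class].
#' @param cfg a [MotionConfig-class].
#' @return The track with motionState set.
#' @export
classifyTrackMotion <- function(track, cfg = MotionConfig()) {
  cents <- t(vapply(track@blobs, function(b) b@centroid, numeric(2)))
  state <- "QUIESCENT"
  if (nrow(cents) > 1L) {
    d2max <- max(stats::dist(cents))
    if (d2max >= cfg@minCentroidDisplacement) state <- "MOTION"
    if (state == "QUIESCENT") {
      a <- track@blobs[[1]]@pixels
      b <- track@blobs[[length(track@blobs)]]@pixels
      symdiff <- length(setdiff(a, b)) + length(setdiff(b, a))
      if (symdiff > 0.2 * mean(c(length(a), length(b)))) state <- "MOTION"
    }
  }
  track@motionState <- state
  track
}
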