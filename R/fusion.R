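## Pipeline step 6 and the live-worm count: fusion of worm-level tracks
## with pixel-level tracks and the three-term daily total.

#' Fuse worm-level tracks into centre pixel-level tracks
#'
#' Each worm-level track is assigned to the pixel-level track containing
#' the majority of its pixels. For every centre (CENTER or MIXED) pixel
#' track, the number of assigned MOTION worm tracks is its live count: the
#' pixel level says something moved there, the worm level says how many
#' worms. A centre pixel track with motion but no assigned worm track at
#' all is floored at one live worm (the pixel level is trusted, as it is
#' in the wall zone); if only quiescent worm tracks are assigned, the
#' fusion contributes 0 and those worms are deferred to the inter-day
#' check.
#'
#' @param pixelTracks list of [PixelTrack-class] (all zones; wall tracks
#'   are ignored here).
#' @param wormTracks list of motion-classified [WormTrack-class].
#' @return List with \code{aTc} (integer per centre pixel track, named by
#'   index into pixelTracks), \code{assignment} (pixel-track index per worm
#'   track, NA if contained in none), and \code{unassignedMotion} (count of
#'   MOTION worm tracks inside no pixel track, each counted as its own
#'   track).
#' @export
fuseTracks <- function(pixelTracks, wormTracks) {
  nP <- length(pixelTracks)
  centerIdx <- which(vapply(pixelTracks, function(p)
    p@zoneClass %in% c("CENTER", "MIXED"), TRUE))
  assignment <- rep(NA_integer_, length(wormTracks))
  if (nP > 0L && length(wormTracks) > 0L) {
    dm <- pixelTracks[[1]]@dim
    lab <- matrix(0L, dm[1], dm[2])
    for (i in seq_len(nP)) lab[pixelTracks[[i]]@pixels] <- i
    for (j in seq_along(wormTracks)) {
      px <- unique(unlist(lapply(wormTracks[[j]]@blobs,
                                 function(b) b@pixels)))
      hits <- lab[px]
      hits <- hits[hits > 0L]
      if (length(hits) > length(px) / 2) {
        tb <- tabulate(hits, nP)
        assignment[j] <- which.max(tb)
      }
    }
  }
  motion <- vapply(wormTracks, function(t) t@motionState == "MOTION", TRUE)
  aTc <- integer(length(centerIdx))
  names(aTc) <- as.character(centerIdx)
  for (k in seq_along(centerIdx)) {
    i <- centerIdx[k]
    assigned <- which(!is.na(assignment) & assignment == i)
    nMotion <- sum(motion[assigned])
    if (length(assigned) == 0L) {
      ## motion at pixel level with no worm-level detection: trust the
      ## pixel level and count one live worm
      aTc[k] <- 1L
    } else {
      aTc[k] <- as.integer(nMotion)
    }
  }
  unassigned <- sum(motion & is.na(assignment))
  if (unassigned > 0L)
    warning(sprintf(
      "%d moving worm track(s) contained in no pixel track; counted individually",
      unassigned))
  list(aTc = aTc, assignment = assignment,
       unassignedMotion = as.integer(unassigned))
}

#' Compose the daily live-worm count
#'
#' The live count for a plate-day is the sum of three terms: one per
#' motion track completely inside the wall zone, the fused live counts of
#' the centre pixel tracks, and the quiescent worms whose shape changed
#' since the previous day.
#'
#' @param wallTracks list of WALL [PixelTrack-class] (or their count).
#' @param fused result of [fuseTracks()] (or an integer vector of a_Tc
#'   values).
#' @param interdayAlive logical vector (one per quiescent worm checked) or
#'   an integer count.
#' @param plateId,day identification recorded on the result.
#' @return A [LiveCount-class].
#' @export
countLiveWorms <- function(wallTracks, fused, interdayAlive,
                           plateId = "plate", day = 0L) {
  nWall <- if (is.numeric(wallTracks)) as.integer(wallTracks)
           else length(wallTracks)
  aTc <- if (is.list(fused)) sum(fused$aTc) + fused$unassignedMotion
         else sum(as.integer(fused))
  nP <- if (is.logical(interdayAlive)) sum(interdayAlive)
        else as.integer(sum(interdayAlive))
  LiveCount(plateId, day, nWall, aTc, nP)
}
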