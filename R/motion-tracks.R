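## Pipeline step 2: wall-zone geodesic dilation of motion pixels, pixel
## level track extraction and zone classification.

#' Bridge wall-zone motion pixels across dark rings
#'
#' Wall-zone MOTION pixels are dilated by a disc of the configured radius
#' (default 40 px native), but only through pixels labelled constant-dark
#' (wall) or noisy: the dilation is geodesic within the dark/noisy rings
#' and never crosses constant-white pixels, so motion fragments of one
#' worm separated by wall shadows join while separate worms across an
#' illuminated ring stay apart. Centre-zone labels are untouched.
#'
#' @param classmap a zone-recoded [PixelClassMap-class].
#' @param zones a [PlateZones-class].
#' @param cfg a [TrackConfig-class].
#' @return Logical mask: bridged wall motion, plus centre MOTION pixels
#'   unchanged.
#' @export
dilateWallMotion <- function(classmap, zones, cfg = TrackConfig()) {
  if (cfg@wallDilationRadius <= 0) stop("wallDilationRadius must be > 0")
  lab <- classmap@labels
  motion <- lab == pixelClasses[["MOTION"]]
  wallMotion <- motion & zones@wallMask
  out <- motion
  if (any(wallMotion)) {
    support <- (lab == pixelClasses[["CONSTANT_DARK_WALL"]] |
                lab == pixelClasses[["NOISY"]]) & zones@wallMask
    bridged <- geodesicDilate(wallMotion, support, cfg@wallDilationRadius)
    out <- motion | bridged
  }
  out
}

#' Extract pixel-level tracks
#'
#' Connected-component labelling with a zone-dependent connectivity
#' alphabet: inside the plate centre, MOTION, CONSTANT_DARK_CENTER and
#' NOISY pixels are equivalent (a quiescent worm touching a moving one
#' belongs to the same track); in the wall zone only the bridged motion
#' mask connects. Components without any MOTION pixel are discarded: every
#' track contains at least one live moving worm.
#'
#' @param classmap a zone-recoded [PixelClassMap-class].
#' @param zones a [PlateZones-class].
#' @param bridged logical mask from [dilateWallMotion()].
#' @return List of [PixelTrack-class], zone-classified.
#' @export
labelPixelTracks <- function(classmap, zones, bridged) {
  lab <- classmap@labels
  centerAlphabet <- zones@centerMask &
    (lab == pixelClasses[["MOTION"]] |
     lab == pixelClasses[["CONSTANT_DARK_CENTER"]] |
     lab == pixelClasses[["NOISY"]])
  connect <- centerAlphabet | (bridged & zones@wallMask)
  comp <- label8(connect)
  n <- max(comp)
  if (n == 0L) return(list())
  motion <- lab == pixelClasses[["MOTION"]]
  tracks <- vector("list", n)
  keep <- logical(n)
  idx <- which(comp > 0L)
  splits <- split(idx, comp[idx])
  for (i in seq_len(n)) {
    px <- splits[[as.character(i)]]
    if (is.null(px)) next
    nm <- sum(motion[px])
    if (nm < 1L) next
    keep[i] <- TRUE
    tr <- new("PixelTrack", pixels = as.integer(px), dim = dim(lab),
              zoneClass = "MIXED", nMotionPixels = as.integer(nm))
    tracks[[i]] <- classifyTrackZone(tr, zones)
  }
  tracks[keep]
}

#' Classify a pixel track's plate zone
#'
#' WALL if every pixel lies in the wall zone, CENTER if every pixel lies in
#' the plate centre, MIXED otherwise. Downstream, WALL tracks each count as
#' one live worm; CENTER and MIXED tracks are resolved at worm level.
#'
#' @param track a [PixelTrack-class].
#' @param zones a [PlateZones-class].
#' @return The track with its zoneClass set.
#' @export
classifyTrackZone <- function(track, zones) {
  inCenter <- zones@centerMask[track@pixels]
  track@zoneClass <- if (all(inCenter)) "CENTER"
    else if (!any(inCenter)) "WALL" else "MIXED"
  track
}
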