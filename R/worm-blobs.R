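## Pipeline step 3: worm-level blob extraction in the plate centre and the
## size / intensity filters.

#' Extract dark blobs in the plate centre
#'
#' 8-connected components of the segmented frame restricted to the plate
#' centre, with intensity statistics read from the original frame. Each
#' component intersecting the centre mask yields one [WormBlob-class]:
#' a possible worm, worm aggregate, or dirt particle.
#'
#' @param mask binary segmented frame (from [segmentFrame()]).
#' @param frame the original grayscale frame.
#' @param zones a [PlateZones-class].
#' @param frameIndex frame number recorded on the blobs.
#' @return List of [WormBlob-class].
#' @export
extractCenterBlobs <- function(mask, frame, zones, frameIndex = 1L) {
  m <- mask == 1L & zones@centerMask
  comp <- label8(m)
  n <- max(comp)
  if (n == 0L) return(list())
  idx <- which(comp > 0L)
  splits <- split(idx, comp[idx])
  dm <- dim(m)
  lapply(splits, function(px) {
    rc <- idxToRowCol(px, dm)
    new("WormBlob", pixels = as.integer(px), dim = dm,
        area = length(px),
        centroid = c(mean(rc[, 1]), mean(rc[, 2])),
        meanIntensity = mean(frame[px]),
        frameIndex = as.integer(frameIndex))
  })
}

#' Size filter for centre blobs
#'
#' Keep a blob iff its area lies in the inclusive band
#' [minArea, maxArea]: from the smallest credible single worm to the
#' biggest credible two-worm aggregate. Smaller blobs are noise or debris;
#' larger ones are aggregates of more than two worms or contamination.
#'
#' @param blob a [WormBlob-class].
#' @param model a [WormModel-class].
#' @return TRUE to keep, FALSE to reject.
#' @export
filterBlobSize <- function(blob, model = WormModel()) {
  blob@area >= model@minArea && blob@area <= model@maxArea
}

#' Intensity filter for worm candidates
#'
#' Worm bodies are darker than grey level 20 under the backlight; blobs
#' with mean intensity at or above the ceiling (dust, lint, lid spots) are
#' rejected. Comparison is strict.
#'
#' @param worm a [WormBlob-class] with meanIntensity set.
#' @param model a [WormModel-class].
#' @return TRUE to keep, FALSE to reject.
#' @export
filterBlobIntensity <- function(worm, model = WormModel()) {
  worm@meanIntensity < model@maxWormIntensity
}
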