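#' @import methods
NULL

## ---- pixel class codes -------------------------------------------------

#' Pixel class codes
#'
#' Integer codes used in [PixelClassMap] label matrices. Before zone
#' recoding, constant-dark pixels carry the generic \code{CONSTANT_DARK}
#' code; [recodeDarkByZone()] splits them into wall and centre variants.
#'
#' @format Named integer vector with elements \code{CONSTANT_DARK},
#'   \code{CONSTANT_WHITE}, \code{NOISY}, \code{MOTION},
#'   \code{CONSTANT_DARK_WALL}, \code{CONSTANT_DARK_CENTER}.
#' @export
pixelClasses <- c(
  CONSTANT_DARK        = 1L,
  CONSTANT_WHITE       = 2L,
  NOISY                = 3L,
  MOTION               = 4L,
  CONSTANT_DARK_WALL   = 5L,
  CONSTANT_DARK_CENTER = 6L
)

## ---- FrameSequence -----------------------------------------------------

#' FrameSequence: one plate-day image sequence
#'
#' Container for the daily observation of one Petri plate: an ordered stack
#' of T grayscale frames (nominally 30 frames at 1 fps) plus plate and day
#' metadata. Frames are stored as an H x W x T numeric array with
#' intensities in [0, 255].
#'
#' @slot plateId character plate identifier.
#' @slot day integer assay day (>= 0).
#' @slot frames numeric array (H, W, T).
#' @slot frameInterval numeric seconds between frames (default 1).
#' @export
setClass("FrameSequence",
  representation(plateId = "character", day = "integer",
                 frames = "array", frameInterval = "numeric"),
  prototype(plateId = "plate", day = 0L, frameInterval = 1))

setValidity("FrameSequence", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L)
    return("frames must be an H x W x T array")
  if (dim(f)[3] < 2L)
    return("a FrameSequence needs at least 2 frames")
  if (anyNA(f) || min(f) < 0 || max(f) > 255)
    return("frame intensities must be finite and in [0, 255]")
  if (object@day < 0L) return("day must be >= 0")
  TRUE
})

#' Construct a FrameSequence
#'
#' @param frames H x W x T numeric array, or a list of equally sized
#'   matrices (stacked in list order).
#' @param plateId plate identifier.
#' @param day assay day index (>= 0).
#' @param frameInterval seconds between frames.
#' @return A [FrameSequence-class] object.
#' @examples
#' fs <- FrameSequence(array(48, c(8, 8, 3)), plateId = "p1", day = 0)
#' nFrames(fs)
#' @export
FrameSequence <- function(frames, plateId = "plate", day = 0, frameInterval = 1) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    c(dims[[1]], length(frames)))
  }
  new("FrameSequence", plateId = as.character(plateId), day = as.integer(day),
      frames = frames, frameInterval = frameInterval)
}

## ---- configuration classes --------------------------------------------

#' Segmentation configuration
#'
#' Parameters for fixed-threshold segmentation and temporal-signature pixel
#' classification. The dark threshold (default 33) separates worms and wall
#' shadows from the backlit background, which the active illumination keeps
#' near grey level 48; no per-image adjustment is needed. A pixel whose
#' binary temporal signature changes more than \code{noiseTransitionThreshold}
#' times across the sequence is classed as noisy rather than in motion.
#'
#' @slot darkThreshold intensity; pixel is dark iff intensity < threshold.
#' @slot backgroundLevel nominal background grey level (informational).
#' @slot noiseTransitionThreshold max signature transitions for MOTION.
#' @slot scale resolution factor relative to the native 1944 x 1944 frames.
#' @export
setClass("SegmentationConfig",
  representation(darkThreshold = "numeric", backgroundLevel = "numeric",
                 noiseTransitionThreshold = "integer", scale = "numeric"),
  prototype(darkThreshold = 33, backgroundLevel = 48,
            noiseTransitionThreshold = 8L, scale = 1))

setValidity("SegmentationConfig", function(object) {
  if (object@darkThreshold <= 0 || object@darkThreshold >= 255)
    return("darkThreshold must be in (0, 255)")
  if (object@noiseTransitionThreshold < 1L)
    return("noiseTransitionThreshold must be >= 1")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})

#' @rdname SegmentationConfig-class
#' @param darkThreshold,backgroundLevel,noiseTransitionThreshold,scale see slots.
#' @export
SegmentationConfig <- function(darkThreshold = 33, backgroundLevel = 48,
                               noiseTransitionThreshold = 8, scale = 1) {
  new("SegmentationConfig", darkThreshold = darkThreshold,
      backgroundLevel = backgroundLevel,
      noiseTransitionThreshold = as.integer(noiseTransitionThreshold),
      scale = scale)
}

#' Pixel-track configuration
#'
#' @slot wallDilationRadius radius (pixels, native scale) of the geodesic
#'   dilation that bridges wall-zone motion pixels across dark rings.
#' @export
setClass("TrackConfig",
  representation(wallDilationRadius = "numeric"),
  prototype(wallDilationRadius = 40))

setValidity("TrackConfig", function(object) {
  if (object@wallDilationRadius <= 0)
    return("wallDilationRadius must be > 0")
  TRUE
})

#' @rdname TrackConfig-class
#' @param wallDilationRadius see slot.
#' @export
TrackConfig <- function(wallDilationRadius = 40)
  new("TrackConfig", wallDilationRadius = wallDilationRadius)

#' Worm shape and intensity model
#'
#' Theoretical single-worm geometry and the blob filters derived from it.
#' Areas are in pixels at native resolution; the size filter keeps blobs
#' with area in [minArea, maxArea] (smallest single worm to biggest two-worm
#' aggregate). Blobs whose area exceeds \code{aggregateMinArea} undergo
#' skeleton-graph disaggregation; smaller blobs are taken as single worms.
#' Worm pixels are expected darker than \code{maxWormIntensity} (strict).
#'
#' @slot theoreticalLength,theoreticalWidth expected worm skeleton length
#'   and body width in pixels.
#' @slot minArea,maxArea inclusive blob-area band in pixels.
#' @slot maxWormIntensity grey-level ceiling for worm blobs (strict <).
#' @slot aggregateMinArea area above which a blob is treated as a possible
#'   two-worm aggregate and disaggregated.
#' @slot maxSkeletonEdges skeletons with more edges are rejected as
#'   aggregates of more than two worms.
#' @export
setClass("WormModel",
  representation(theoreticalLength = "numeric", theoreticalWidth = "numeric",
                 minArea = "numeric", maxArea = "numeric",
                 maxWormIntensity = "numeric", aggregateMinArea = "numeric",
                 maxSkeletonEdges = "integer"),
  prototype(theoreticalLength = 85, theoreticalWidth = 2.8,
            minArea = 20, maxArea = 240, maxWormIntensity = 20,
            aggregateMinArea = 150, maxSkeletonEdges = 12L))

setValidity("WormModel", function(object) {
  if (object@minArea >= object@maxArea)
    return("minArea must be < maxArea")
  if (object@theoreticalLength <= 0 || object@theoreticalWidth <= 0)
    return("theoretical worm dimensions must be positive")
  TRUE
})

#' @rdname WormModel-class
#' @param theoreticalLength,theoreticalWidth,minArea,maxArea see slots.
#' @param maxWormIntensity,aggregateMinArea,maxSkeletonEdges see slots.
#' @param scale resolution factor; areas scale with scale^2, lengths with
#'   scale.
#' @export
WormModel <- function(theoreticalLength = 85, theoreticalWidth = 2.8,
                      minArea = 20, maxArea = 240, maxWormIntensity = 20,
                      aggregateMinArea = 1.5 * theoreticalLength * theoreticalWidth,
                      maxSkeletonEdges = 12, scale = 1) {
  new("WormModel",
      theoreticalLength = theoreticalLength * scale,
      theoreticalWidth = theoreticalWidth * scale,
      minArea = minArea * scale^2, maxArea = maxArea * scale^2,
      maxWormIntensity = maxWormIntensity,
      aggregateMinArea = aggregateMinArea * scale^2,
      maxSkeletonEdges = as.integer(maxSkeletonEdges))
}

#' Motion and inter-day comparison configuration
#'
#' @slot minCentroidDisplacement pixels: a worm track whose maximum
#'   centroid displacement across the sequence reaches this value is in
#'   motion.
#' @slot matchScoreThreshold normalized match score at or above which a
#'   quiescent worm is considered unchanged since the previous day (dead).
#' @slot maxAlignmentRotation,maxAlignmentTranslation bounds (degrees,
#'   pixels) on the inter-day rigid alignment search.
#' @slot matchSearchRadius pixels of local translation allowed when
#'   matching a quiescent worm's sub-image across days.
#' @export
setClass("MotionConfig",
  representation(minCentroidDisplacement = "numeric",
                 matchScoreThreshold = "numeric",
                 maxAlignmentRotation = "numeric",
                 maxAlignmentTranslation = "numeric",
                 matchSearchRadius = "numeric"),
  prototype(minCentroidDisplacement = 5, matchScoreThreshold = 0.90,
            maxAlignmentRotation = 5, maxAlignmentTranslation = 60,
            matchSearchRadius = 3))

setValidity("MotionConfig", function(object) {
  if (object@matchScoreThreshold <= 0 || object@matchScoreThreshold >= 1)
    return("matchScoreThreshold must be in (0, 1)")
  TRUE
})

#' @rdname MotionConfig-class
#' @param minCentroidDisplacement,matchScoreThreshold see slots.
#' @param maxAlignmentRotation,maxAlignmentTranslation,matchSearchRadius see slots.
#' @param scale resolution factor applied to pixel-denominated fields.
#' @export
MotionConfig <- function(minCentroidDisplacement = 5,
                         matchScoreThreshold = 0.90,
                         maxAlignmentRotation = 5,
                         maxAlignmentTranslation = 60,
                         matchSearchRadius = 3, scale = 1) {
  new("MotionConfig",
      minCentroidDisplacement = minCentroidDisplacement * scale,
      matchScoreThreshold = matchScoreThreshold,
      maxAlignmentRotation = maxAlignmentRotation,
      maxAlignmentTranslation = maxAlignmentTranslation * scale,
      matchSearchRadius = matchSearchRadius)
}

#' Curve filter configuration
#'
#' @slot dividingDay the assay day separating the filter's first period
#'   (errors treated as false negatives, counts raised) from the second
#'   (errors treated as false positives, counts clamped). Choose the
#'   strain's mean lifespan (N2: 14, daf-2: 42).
#' @export
setClass("FilterConfig", representation(dividingDay = "numeric"),
         prototype(dividingDay = 14))

#' @rdname FilterConfig-class
#' @param dividingDay see slot.
#' @export
FilterConfig <- function(dividingDay = 14)
  new("FilterConfig", dividingDay = dividingDay)

## ---- derived data classes ---------------------------------------------

#' Per-pixel temporal class map
#'
#' Label image over a stacked frame sequence: each plate pixel carries
#' exactly one of the codes in [pixelClasses].
#'
#' @slot labels integer H x W matrix of pixel class codes.
#' @slot config the [SegmentationConfig-class] used (provenance).
#' @export
setClass("PixelClassMap",
  representation(labels = "matrix", config = "SegmentationConfig"))

setValidity("PixelClassMap", function(object) {
  if (!all(object@labels %in% pixelClasses))
    return("labels must be pixelClasses codes")
  TRUE
})

#' Plate zone partition
#'
#' @slot centerMask,wallMask logical H x W masks; disjoint, covering the
#'   image. The centre is the filled largest constant-white component.
#' @slot edgeContour integer matrix (n x 2, row/col) of boundary pixels of
#'   the centre mask.
#' @export
setClass("PlateZones",
  representation(centerMask = "matrix", wallMask = "matrix",
                 edgeContour = "matrix"))

setValidity("PlateZones", function(object) {
  if (any(object@centerMask & object@wallMask))
    return("centerMask and wallMask must be disjoint")
  if (!any(object@centerMask)) return("centre area must be > 0")
  TRUE
})

#' Pixel-level motion track
#'
#' A connected region containing motion, with its plate-zone class. Tracks
#' completely inside the wall zone (WALL) are counted as one live worm
#' each; CENTER and MIXED tracks are resolved at worm level.
#'
#' @slot pixels integer vector of linear pixel indices into the H x W grid.
#' @slot dim integer image dimensions.
#' @slot zoneClass one of "WALL", "CENTER", "MIXED".
#' @slot nMotionPixels number of MOTION-labelled pixels in the track.
#' @export
setClass("PixelTrack",
  representation(pixels = "integer", dim = "integer", zoneClass = "character",
                 nMotionPixels = "integer"))

setValidity("PixelTrack", function(object) {
  if (length(object@pixels) == 0L) return("track must be non-empty")
  if (object@nMotionPixels < 1L) return("track must contain a MOTION pixel")
  if (!object@zoneClass %in% c("WALL", "CENTER", "MIXED"))
    return("zoneClass must be WALL, CENTER or MIXED")
  TRUE
})

#' Worm-level blob
#'
#' One dark connected component in the plate centre of a single frame, with
#' shape and intensity measurements. Length and width are filled in by
#' skeleton analysis and may be NA for blobs taken as single worms without
#' it.
#'
#' @slot pixels integer vector of linear pixel indices.
#' @slot dim integer image dimensions.
#' @slot area pixels.
#' @slot centroid numeric (row, col).
#' @slot meanIntensity mean grey level over the blob in the source frame.
#' @slot length,width skeleton-based measurements (pixels).
#' @slot frameIndex frame of origin.
#' @export
setClass("WormBlob",
  representation(pixels = "integer", dim = "integer", area = "numeric",
                 centroid = "numeric", meanIntensity = "numeric",
                 length = "numeric", width = "numeric", frameIndex = "integer"),
  prototype(length = NA_real_, width = NA_real_, frameIndex = 1L))

setValidity("WormBlob", function(object) {
  if (object@area <= 0) return("area must be > 0")
  if (!is.na(object@meanIntensity) &&
      (object@meanIntensity < 0 || object@meanIntensity > 255))
    return("meanIntensity must be in [0, 255]")
  TRUE
})

#' Skeleton graph of a blob
#'
#' Topological skeleton partitioned into nodes (degree-1 endpoints,
#' degree >= 3 crosses, adjacent cross pixels merged) and edges (arcs of
#' skeleton pixels connecting nodes) with geodesic lengths and mean local
#' widths from the blob's distance transform.
#'
#' @slot nodes data.frame with columns id, row, col, type ("end"/"cross").
#' @slot edges list; each element a list with fields from, to (node ids),
#'   pixels (n x 2 matrix), length, width.
#' @slot dim integer image dimensions of the source crop.
#' @slot offset integer (row, col) offset of the crop in the source frame
#'   (crop coordinate + offset = frame coordinate).
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", edges = "list", dim = "integer",
                 offset = "integer"),
  prototype(offset = c(0L, 0L)))

#' Worm-level track
#'
#' Chain of per-frame worm blobs linked by spatial overlap, with a motion
#' verdict over the sequence.
#'
#' @slot blobs list of [WormBlob-class], ordered by frame.
#' @slot frames integer frame indices (parallel to blobs).
#' @slot motionState "MOTION" or "QUIESCENT".
#' @slot pixelTrackId index of the containing pixel-level track (NA if
#'   none).
#' @export
setClass("WormTrack",
  representation(blobs = "list", frames = "integer", motionState = "character",
                 pixelTrackId = "integer"),
  prototype(motionState = "QUIESCENT", pixelTrackId = NA_integer_))

#' Rigid 2-D transform between consecutive-day images
#'
#' Maps previous-day coordinates onto current-day coordinates:
#' p_curr = R(theta) (p_prev - c) + c + t, rotating about the image centre
#' c.
#'
#' @slot angle rotation in degrees.
#' @slot tx,ty translation in pixels (row, col offsets).
#' @slot score intensity agreement (normalized cross-correlation) achieved.
#' @export
setClass("RigidTransform",
  representation(angle = "numeric", tx = "numeric", ty = "numeric",
                 score = "numeric"),
  prototype(angle = 0, tx = 0, ty = 0, score = NA_real_))

#' @rdname RigidTransform-class
#' @param angle,tx,ty,score see slots.
#' @export
RigidTransform <- function(angle = 0, tx = 0, ty = 0, score = NA_real_)
  new("RigidTransform", angle = angle, tx = tx, ty = ty, score = score)

#' Daily live-worm count decomposition
#'
#' The live count a_is for one plate-day is the sum of three terms: one per
#' wall-zone motion track, the number of moving worm-level tracks fused
#' into each centre pixel-track, and quiescent worms whose shape changed
#' since the previous day.
#'
#' @slot plateId,day identification.
#' @slot nWallTracks,nCenterAlive,nInterdayAlive the three terms.
#' @export
setClass("LiveCount",
  representation(plateId = "character", day = "integer",
                 nWallTracks = "integer", nCenterAlive = "integer",
                 nInterdayAlive = "integer"))

setValidity("LiveCount", function(object) {
  if (any(c(object@nWallTracks, object@nCenterAlive,
            object@nInterdayAlive) < 0L))
    return("all count terms must be >= 0")
  TRUE
})

#' @rdname LiveCount-class
#' @param plateId,day,nWallTracks,nCenterAlive,nInterdayAlive see slots.
#' @export
LiveCount <- function(plateId, day, nWallTracks, nCenterAlive, nInterdayAlive)
  new("LiveCount", plateId = as.character(plateId), day = as.integer(day),
      nWallTracks = as.integer(nWallTracks),
      nCenterAlive = as.integer(nCenterAlive),
      nInterdayAlive = as.integer(nInterdayAlive))

#' Lifespan curve for one plate
#'
#' Per-day live counts with the initial population. Raw automated curves
#' may violate monotonicity; [adaptiveFilter()] repairs them.
#'
#' @slot plateId plate identifier.
#' @slot n0 initial worm count.
#' @slot days strictly increasing integer day grid.
#' @slot counts integer live counts per day.
#' @slot censored logical per day (missing/contaminated observations).
#' @export
setClass("LifespanCurve",
  representation(plateId = "character", n0 = "integer", days = "integer",
                 counts = "integer", censored = "logical"))

setValidity("LifespanCurve", function(object) {
  if (length(object@days) != length(object@counts) ||
      length(object@days) != length(object@censored))
    return("days, counts and censored must be parallel")
  if (length(object@days) > 1L && any(diff(object@days) <= 0L))
    return("days must be strictly increasing")
  if (any(object@counts < 0L)) return("counts must be >= 0")
  TRUE
})

#' @rdname LifespanCurve-class
#' @param plateId,n0,days,counts,censored see slots.
#' @export
LifespanCurve <- function(plateId, n0, days, counts,
                          censored = rep(FALSE, length(days))) {
  new("LifespanCurve", plateId = as.character(plateId), n0 = as.integer(n0),
      days = as.integer(days), counts = as.integer(counts),
      censored = as.logical(censored))
}

## ---- pipeline configuration -------------------------------------------

#' Full pipeline configuration
#'
#' Composition of all stage configurations plus the resolution scale. Use
#' [PipelineConfig()] to build one with consistently scaled pixel
#' parameters, and [validateConfig()] to check cross-field consistency.
#'
#' @slot segmentation,track,wormModel,motion,filter stage configs.
#' @slot scale resolution factor relative to native 1944 x 1944.
#' @export
setClass("PipelineConfig",
  representation(segmentation = "SegmentationConfig", track = "TrackConfig",
                 wormModel = "WormModel", motion = "MotionConfig",
                 filter = "FilterConfig", scale = "numeric"))

#' @rdname PipelineConfig-class
#' @param scale resolution factor; pixel-denominated defaults in the stage
#'   configs are multiplied by scale (lengths/radii) or scale^2 (areas).
#' @param segmentation,track,wormModel,motion,filter pre-built stage
#'   configs; defaults are constructed at the given scale.
#' @export
PipelineConfig <- function(scale = 1,
                           segmentation = SegmentationConfig(scale = scale),
                           track = TrackConfig(wallDilationRadius = 40 * scale),
                           wormModel = WormModel(scale = scale),
                           motion = MotionConfig(scale = scale),
                           filter = FilterConfig()) {
  new("PipelineConfig", segmentation = segmentation, track = track,
      wormModel = wormModel, motion = motion, filter = filter, scale = scale)
}
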