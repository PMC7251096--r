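## Accessor generics and show methods for the core classes.

#' @name accessors
#' @title Accessors for wormspan classes
#' @param object an object of the documented class.
#' @description Small accessor functions exposing slots of the S4 data
#'   classes without direct slot access.
NULL

#' @rdname accessors
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))
#' @rdname accessors
#' @export
setGeneric("assayDay", function(object) standardGeneric("assayDay"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("centerMask", function(object) standardGeneric("centerMask"))
#' @rdname accessors
#' @export
setGeneric("wallMask", function(object) standardGeneric("wallMask"))
#' @rdname accessors
#' @export
setGeneric("zoneClass", function(object) standardGeneric("zoneClass"))
#' @rdname accessors
#' @export
setGeneric("motionState", function(object) standardGeneric("motionState"))
#' @rdname accessors
#' @export
setGeneric("liveTotal", function(object) standardGeneric("liveTotal"))
#' @rdname accessors
#' @export
setGeneric("curveDays", function(object) standardGeneric("curveDays"))
#' @rdname accessors
#' @export
setGeneric("curveCounts", function(object) standardGeneric("curveCounts"))
#' @rdname accessors
#' @export
setGeneric("initialCount", function(object) standardGeneric("initialCount"))
#' @rdname accessors
#' @export
setGeneric("censored", function(object) standardGeneric("censored"))

#' @rdname accessors
#' @export
setMethod("plateId", "FrameSequence", function(object) object@plateId)
#' @rdname accessors
#' @export
setMethod("plateId", "LifespanCurve", function(object) object@plateId)
#' @rdname accessors
#' @export
setMethod("plateId", "LiveCount", function(object) object@plateId)
#' @rdname accessors
#' @export
setMethod("assayDay", "FrameSequence", function(object) object@day)
#' @rdname accessors
#' @export
setMethod("assayDay", "LiveCount", function(object) object@day)
#' @rdname accessors
#' @export
setMethod("frames", "FrameSequence", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(object) dim(object@frames)[3])
#' @rdname accessors
#' @export
setMethod("classLabels", "PixelClassMap", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("centerMask", "PlateZones", function(object) object@centerMask)
#' @rdname accessors
#' @export
setMethod("wallMask", "PlateZones", function(object) object@wallMask)
#' @rdname accessors
#' @export
setMethod("zoneClass", "PixelTrack", function(object) object@zoneClass)
#' @rdname accessors
#' @export
setMethod("motionState", "WormTrack", function(object) object@motionState)
#' @rdname accessors
#' @export
setMethod("liveTotal", "LiveCount", function(object)
  object@nWallTracks + object@nCenterAlive + object@nInterdayAlive)
#' @rdname accessors
#' @export
setMethod("curveDays", "LifespanCurve", function(object) object@days)
#' @rdname accessors
#' @export
setMethod("curveCounts", "LifespanCurve", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("initialCount", "LifespanCurve", function(object) object@n0)
#' @rdname accessors
#' @export
setMethod("censored", "LifespanCurve", function(object) object@censored)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence plate '%s' day %d: %d frames of %d x %d\n",
              object@plateId, object@day, d[3], d[1], d[2]))
})

setMethod("show", "PixelClassMap", function(object) {
  tab <- table(factor(object@labels, levels = pixelClasses,
                      labels = names(pixelClasses)))
  cat(sprintf("PixelClassMap %d x %d\n", nrow(object@labels),
              ncol(object@labels)))
  print(tab[tab > 0])
})

setMethod("show", "PlateZones", function(object) {
  cat(sprintf("PlateZones: centre %d px, wall %d px\n",
              sum(object@centerMask), sum(object@wallMask)))
})

setMethod("show", "PixelTrack", function(object) {
  cat(sprintf("PixelTrack (%s): %d px, %d in motion\n", object@zoneClass,
              length(object@pixels), object@nMotionPixels))
})

setMethod("show", "WormBlob", function(object) {
  cat(sprintf(
    "WormBlob frame %d: area %.0f, centroid (%.1f, %.1f), mean grey %.1f\n",
    object@frameIndex, object@area, object@centroid[1], object@centroid[2],
    object@meanIntensity))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d nodes (%d ends, %d crosses), %d edges\n",
              nrow(object@nodes), sum(object@nodes$type == "end"),
              sum(object@nodes$type == "cross"), length(object@edges)))
})

setMethod("show", "WormTrack", function(object) {
  cat(sprintf("WormTrack (%s): %d blobs over frames %d..%d\n",
              object@motionState, length(object@blobs),
              min(object@frames), max(object@frames)))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: angle %.2f deg, t = (%.2f, %.2f), score %.3f\n",
              object@angle, object@tx, object@ty, object@score))
})

setMethod("show", "LiveCount", function(object) {
  cat(sprintf("LiveCount plate '%s' day %d: %d = %d wall + %d centre + %d inter-day\n",
              object@plateId, object@day, liveTotal(object),
              object@nWallTracks, object@nCenterAlive, object@nInterdayAlive))
})

setMethod("show", "LifespanCurve", function(object) {
  cat(sprintf("LifespanCurve plate '%s' (n0 = %d), days %s..%s\n",
              object@plateId, object@n0,
              if (length(object@days)) min(object@days) else "-",
              if (length(object@days)) max(object@days) else "-"))
  if (length(object@days)) {
    df <- data.frame(day = object@days, count = object@counts,
                     censored = object@censored)
    print(utils::head(df, 10))
    if (nrow(df) > 10) cat("...\n")
  }
})

#' Convert a LifespanCurve to a data.frame
#'
#' @param x a [LifespanCurve-class].
#' @param ... unused.
#' @return data.frame with columns plate_id, day, count, censored.
#' @export
setMethod("as.data.frame", "LifespanCurve", function(x, ...) {
  data.frame(plate_id = rep(x@plateId, length(x@days)), day = x@days,
             count = x@counts, censored = x@censored,
             stringsAsFactors = FALSE)
})
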