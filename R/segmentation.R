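## Pipeline step 1: fixed-threshold segmentation, temporal-signature
## stacking, pixel classification and plate-zone partitioning.

#' Segment one frame with the fixed dark threshold
#'
#' A pixel is foreground (dark: worm, wall shadow, dirt) iff its intensity
#' is strictly below the configured threshold (default 33). The active
#' backlight keeps the background near grey level 48, so no per-image
#' threshold adjustment is needed.
#'
#' @param frame numeric matrix with intensities in [0, 255].
#' @param cfg a [SegmentationConfig-class].
#' @return Integer matrix of 0/1 (1 = dark foreground).
#' @examples
#' segmentFrame(matrix(c(0, 32, 33, 48), 2), SegmentationConfig())
#' @export
segmentFrame <- function(frame, cfg = SegmentationConfig()) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop("frame must be a non-empty 2-D matrix")
  out <- matrix(0L, nrow(frame), ncol(frame))
  out[frame < cfg@darkThreshold] <- 1L
  out
}

#' Stack per-frame segmentations into a temporal-signature stack
#'
#' Segments every frame of a sequence and stacks the binary images into a
#' (H, W, T) array. The T-vector at each pixel is its temporal signature.
#'
#' @param seq a [FrameSequence-class].
#' @param cfg a [SegmentationConfig-class].
#' @return Integer 0/1 array of shape (H, W, T).
#' @export
stackSignatures <- function(seq, cfg = SegmentationConfig()) {
  stopifnot(is(seq, "FrameSequence"))
  f <- seq@frames
  stack <- array(0L, dim(f))
  stack[f < cfg@darkThreshold] <- 1L
  stack
}

#' Classify one temporal signature
#'
#' All-dark signatures are CONSTANT_DARK, all-white CONSTANT_WHITE.
#' Otherwise the number of value transitions k = #\{t: s[t] != s[t+1]\}
#' decides: k <= noiseTransitionThreshold is MOTION (a worm crossing a
#' pixel changes it few times), larger k is NOISY (sensor or condensation
#' flicker switches at high frequency).
#'
#' @param signature binary vector (length T >= 2).
#' @param cfg a [SegmentationConfig-class].
#' @return One of "CONSTANT_DARK", "CONSTANT_WHITE", "MOTION", "NOISY".
#' @examples
#' classifySignature(rep(1, 30))
#' classifySignature(rep(0:1, 15))   # 29 transitions -> NOISY
#' @export
classifySignature <- function(signature, cfg = SegmentationConfig()) {
  if (length(signature) < 2L) stop("signature must have length >= 2")
  if (all(signature == 1)) return("CONSTANT_DARK")
  if (all(signature == 0)) return("CONSTANT_WHITE")
  k <- sum(signature[-1] != signature[-length(signature)])
  if (k <= cfg@noiseTransitionThreshold) "MOTION" else "NOISY"
}

#' Classify every pixel of a signature stack
#'
#' Vectorised per-pixel application of [classifySignature()] over a stacked
#' sequence. Constant-dark pixels carry the generic code until
#' [recodeDarkByZone()] splits them by plate zone.
#'
#' @param stack binary (H, W, T) array from [stackSignatures()].
#' @param cfg a [SegmentationConfig-class].
#' @return A [PixelClassMap-class].
#' @export
classifyPixels <- function(stack, cfg = SegmentationConfig()) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] >= 2L)
  d <- dim(stack)
  nDark <- rowSums(stack, dims = 2)
  trans <- matrix(0L, d[1], d[2])
  for (t in seq_len(d[3] - 1L))
    trans <- trans + (stack[, , t] != stack[, , t + 1L])
  lab <- matrix(pixelClasses[["NOISY"]], d[1], d[2])
  lab[trans <= cfg@noiseTransitionThreshold] <- pixelClasses[["MOTION"]]
  lab[nDark == d[3]] <- pixelClasses[["CONSTANT_DARK"]]
  lab[nDark == 0L] <- pixelClasses[["CONSTANT_WHITE"]]
  new("PixelClassMap", labels = lab, config = cfg)
}

#' Detect the plate centre and wall zones
#'
#' The centre is the largest 8-connected CONSTANT_WHITE component, with
#' holes filled (worms and dirt punch holes in the white blob but belong to
#' the centre); everything else is the wall zone. The centre boundary is
#' the plate-wall edge contour.
#'
#' @param classmap a [PixelClassMap-class] (pre- or post-recoding).
#' @return A [PlateZones-class].
#' @export
detectZones <- function(classmap) {
  lab <- classmap@labels
  white <- lab == pixelClasses[["CONSTANT_WHITE"]]
  if (!any(white)) stop("no plate centre detected (no constant-white pixel)")
  comp <- label8(white)
  areas <- tabulate(comp[comp > 0L])
  center <- comp == which.max(areas)
  center <- EBImage::fillHull(matrix(as.numeric(center), nrow(center))) > 0
  center <- matrix(center, nrow(lab), ncol(lab))
  wall <- !center
  # boundary: centre pixels with a non-centre 4-neighbour (or image edge)
  inner <- center &
    shiftMat(center, 1, 0, TRUE) & shiftMat(center, -1, 0, TRUE) &
    shiftMat(center, 0, 1, TRUE) & shiftMat(center, 0, -1, TRUE)
  contour <- which(center & !inner, arr.ind = TRUE)
  colnames(contour) <- c("row", "col")
  new("PlateZones", centerMask = center, wallMask = wall,
      edgeContour = contour)
}

#' Split constant-dark pixels by plate zone
#'
#' Recode CONSTANT_DARK pixels as CONSTANT_DARK_WALL (wall zone;
#' conventionally rendered black) or CONSTANT_DARK_CENTER (plate centre;
#' rendered green).
#' Other labels are unchanged.
#'
#' @param classmap a [PixelClassMap-class].
#' @param zones a [PlateZones-class] of the same shape.
#' @return The recoded [PixelClassMap-class].
#' @export
recodeDarkByZone <- function(classmap, zones) {
  lab <- classmap@labels
  if (!all(dim(lab) == dim(zones@centerMask)))
    stop("classmap and zones have mismatched shapes")
  dark <- lab == pixelClasses[["CONSTANT_DARK"]]
  lab[dark & zones@centerMask] <- pixelClasses[["CONSTANT_DARK_CENTER"]]
  lab[dark & zones@wallMask] <- pixelClasses[["CONSTANT_DARK_WALL"]]
  new("PixelClassMap", labels = lab, config = classmap@config)
}

#' Export a class map as an indexed colour PNG
#'
#' Visual-debug rendering with the conventional colour coding: black
#' (constant dark, wall), green (constant dark, centre), white (constant
#' white), blue (noisy), red (motion).
#'
#' @param classmap a [PixelClassMap-class].
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
writeClassMapPng <- function(classmap, path) {
  lab <- classmap@labels
  pal <- rbind(
    CONSTANT_DARK        = c(0, 0, 0),
    CONSTANT_WHITE       = c(1, 1, 1),
    NOISY                = c(0, 0, 1),
    MOTION               = c(1, 0, 0),
    CONSTANT_DARK_WALL   = c(0, 0, 0),
    CONSTANT_DARK_CENTER = c(0, 1, 0))
  idx <- match(lab, pixelClasses[rownames(pal)])
  img <- array(0, c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[idx, ch], nrow(lab))
  png::writePNG(img, path)
  invisible(path)
}
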