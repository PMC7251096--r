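## End-to-end orchestration of the seven pipeline steps, configuration
## validation, and frame-directory input.

#' Validate a pipeline configuration
#'
#' Checks all stage invariants plus cross-field ordering (worm intensity
#' ceiling < dark threshold < background level). All violations are
#' returned, not just the first.
#'
#' @param cfg a [PipelineConfig-class].
#' @return Character vector of violations; empty if the configuration is
#'   valid.
#' @examples
#' validateConfig(PipelineConfig())   # character(0)
#' @export
validateConfig <- function(cfg) {
  v <- character()
  chk <- function(obj) {
    res <- try(validObject(obj), silent = TRUE)
    if (inherits(res, "try-error"))
      v <<- c(v, conditionMessage(attr(res, "condition")))
  }
  chk(cfg@segmentation); chk(cfg@track); chk(cfg@wormModel)
  chk(cfg@motion); chk(cfg@filter)
  if (cfg@scale <= 0) v <- c(v, "scale must be positive")
  if (cfg@wormModel@maxWormIntensity >= cfg@segmentation@darkThreshold)
    v <- c(v, "worm intensity ceiling must be below the dark threshold")
  if (cfg@segmentation@darkThreshold >= cfg@segmentation@backgroundLevel)
    v <- c(v, "dark threshold must be below the background level")
  if (cfg@track@wallDilationRadius <= 0)
    v <- c(v, "wallDilationRadius must be > 0")
  v
}

#' Process one plate-day sequence
#'
#' Runs the seven pipeline steps on a single [FrameSequence-class]:
#' signature stacking and pixel classification, zone detection, wall-zone
#' bridging and pixel-track extraction, centre blob detection with size
#' filtering, disaggregation and intensity filtering, worm tracking and
#' motion classification, track fusion, and (when a previous day is
#' available) inter-day alignment and death checks for quiescent worms.
#'
#' @param seq a [FrameSequence-class].
#' @param cfg a [PipelineConfig-class].
#' @param prevState state list returned by a previous call for the same
#'   plate (or NULL on the first day): representative and last frames of
#'   the previous sequence.
#' @return List with \code{liveCount} ([LiveCount-class]), \code{state}
#'   (to pass to the next day), and \code{details} (tracks and transform).
#' @export
processPlateDay <- function(seq, cfg = PipelineConfig(), prevState = NULL) {
  segcfg <- cfg@segmentation
  stack <- stackSignatures(seq, segcfg)
  classmap <- classifyPixels(stack, segcfg)
  zones <- detectZones(classmap)
  classmap <- recodeDarkByZone(classmap, zones)
  bridged <- dilateWallMotion(classmap, zones, cfg@track)
  pixelTracks <- labelPixelTracks(classmap, zones, bridged)
  wall <- sum(vapply(pixelTracks, function(t) t@zoneClass == "WALL", TRUE))

  ## worm level, per frame
  T <- nFrames(seq)
  perFrame <- vector("list", T)
  for (t in seq_len(T)) {
    frame <- seq@frames[, , t]
    mask <- matrix(stack[, , t], nrow(frame))
    blobs <- extractCenterBlobs(mask, frame, zones, frameIndex = t)
    blobs <- Filter(function(b) filterBlobSize(b, cfg@wormModel), blobs)
    worms <- list()
    for (b in blobs) {
      ws <- tryCatch(disaggregate(b, cfg@wormModel, frame),
                     wormspanSkeletonError = function(e) list())
      worms <- c(worms, Filter(function(w)
        filterBlobIntensity(w, cfg@wormModel), ws))
    }
    perFrame[[t]] <- worms
  }
  wormTracks <- trackWorms(perFrame)
  wormTracks <- lapply(wormTracks, classifyTrackMotion, cfg = cfg@motion)
  fused <- fuseTracks(pixelTracks, wormTracks)

  ## inter-day death checks for quiescent worms
  transform <- RigidTransform()
  interday <- logical(0)
  quiescent <- Filter(function(t) t@motionState == "QUIESCENT", wormTracks)
  if (!is.null(prevState) && length(quiescent) > 0L) {
    transform <- alignImages(prevState$rep, representativeFrame(seq),
                             cfg@motion)
    lastFrame <- seq@frames[, , T]
    interday <- vapply(quiescent, function(tr)
      detectInterdayMotion(tr, lastFrame, prevState$last, transform,
                           cfg@motion, segcfg)$alive, TRUE)
  }
  lc <- countLiveWorms(wall, fused, interday, plateId = seq@plateId,
                       day = seq@day)
  list(liveCount = lc,
       state = list(rep = representativeFrame(seq),
                    last = seq@frames[, , T]),
       details = list(nPixelTracks = length(pixelTracks),
                      nWormTracks = length(wormTracks),
                      nQuiescent = length(quiescent),
                      transform = transform))
}

## alignDays on bare representative frames (internal; alignDays wraps it
## for FrameSequence input).
alignImages <- function(prevRep, currRep, cfg) {
  prevSeq <- FrameSequence(array(rep(prevRep, 2), c(dim(prevRep), 2)))
  currSeq <- FrameSequence(array(rep(currRep, 2), c(dim(currRep), 2)))
  alignDays(currSeq, prevSeq, cfg)
}

#' Run the full processing pipeline over an assay
#'
#' Processes every plate-day of an input source in day order, carrying the
#' previous day's state for the inter-day death checks, and assembles one
#' raw lifespan curve per plate. Day 0 has no inter-day term. A failing
#' plate-day is recorded as censored and processing continues; results are
#' a pure function of (input, config).
#'
#' @param input a [SimulatedAssay-class], or a directory root laid out as
#'   \code{<root>/<plate_id>/day<NN>/frame<TT>.png}.
#' @param cfg a [PipelineConfig-class].
#' @param n0 initial worm count per plate (scalar or named vector by
#'   plate id). For a simulated assay, defaults to its configured worm
#'   count.
#' @param verbose print per-plate-day progress.
#' @return List with \code{curves} (named list of raw
#'   [LifespanCurve-class]), \code{log} (data.frame of per-day count
#'   terms), and \code{errors} (per-plate-day failure records).
#' @export
runProcess <- function(input, cfg = PipelineConfig(), n0 = NULL,
                       verbose = FALSE) {
  viol <- validateConfig(cfg)
  if (length(viol)) stop("invalid configuration: ",
                         paste(viol, collapse = "; "))
  src <- inputSource(input)
  if (is.null(n0)) n0 <- src$defaultN0
  logRows <- list()
  errors <- list()
  curves <- list()
  for (pid in src$plates) {
    state <- NULL
    daily <- list()
    for (day in src$days(pid)) {
      res <- tryCatch({
        seq <- src$read(pid, day)
        processPlateDay(seq, cfg, prevState = state)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- list(plate = pid, day = day,
                                              message = conditionMessage(res))
        state <- NULL   # alignment chain broken; flag and continue
        next
      }
      state <- res$state
      lc <- res$liveCount
      daily[[length(daily) + 1L]] <- lc
      logRows[[length(logRows) + 1L]] <- data.frame(
        plate_id = pid, day = day, wall = lc@nWallTracks,
        center = lc@nCenterAlive, interday = lc@nInterdayAlive,
        total = liveTotal(lc))
      if (verbose)
        message(sprintf("%s day %d: %d live (%d wall + %d centre + %d interday)",
                        pid, day, liveTotal(lc), lc@nWallTracks,
                        lc@nCenterAlive, lc@nInterdayAlive))
    }
    pn0 <- if (length(n0) > 1L) n0[[pid]] else n0
    curves[[pid]] <- assembleCurve(daily, n0 = pn0)
  }
  list(curves = curves,
       log = if (length(logRows)) do.call(rbind, logRows) else
         data.frame(plate_id = character(), day = integer(),
                    wall = integer(), center = integer(),
                    interday = integer(), total = integer()),
       errors = errors)
}

## Uniform access to the two input kinds.
inputSource <- function(input) {
  if (is(input, "SimulatedAssay")) {
    list(plates = input@plateIds,
         days = function(pid) input@days,
         read = function(pid, day) frameSequence(input, pid, day),
         defaultN0 = input@config@nWorms)
  } else if (is.character(input) && dir.exists(input)) {
    plates <- sort(list.dirs(input, recursive = FALSE, full.names = FALSE))
    if (length(plates) == 0L) stop("empty input directory: ", input)
    list(plates = plates,
         days = function(pid) {
           dd <- sort(list.dirs(file.path(input, pid), recursive = FALSE,
                                full.names = FALSE))
           as.integer(sub("^day", "", dd))
         },
         read = function(pid, day)
           readFrameSequence(file.path(input, pid, sprintf("day%02d", day)),
                             plateId = pid, day = day),
         defaultN0 = NA_integer_)
  } else stop("input must be a SimulatedAssay or an existing directory")
}

#' Read a frame sequence from files
#'
#' Reads a directory of lexicographically ordered PNG/TIFF frames, or a
#' multi-page TIFF file. 8-bit grayscale expected; RGB images are
#' converted by luminance.
#'
#' @param path directory of frames or a multi-page TIFF.
#' @param plateId,day metadata for the sequence.
#' @return A [FrameSequence-class].
#' @export
readFrameSequence <- function(path, plateId = "plate", day = 0) {
  toGray <- function(img) {
    if (length(dim(img)) == 3L)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    img * 255
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) stop("need at least 2 frames in ", path)
    mats <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) toGray(png::readPNG(f))
      else {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("package 'tiff' needed to read TIFF frames")
        toGray(tiff::readTIFF(f))
      }
    })
    FrameSequence(mats, plateId = plateId, day = day)
  } else if (file.exists(path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' needed to read TIFF frames")
    pages <- tiff::readTIFF(path, all = TRUE)
    FrameSequence(lapply(pages, toGray), plateId = plateId, day = day)
  } else stop("no such frame source: ", path)
}

#' Write a frame sequence as PNG files
#'
#' @param seq a [FrameSequence-class].
#' @param dir output directory (created if needed); frames are written as
#'   \code{frame01.png} onwards.
#' @return Invisibly, the directory.
#' @export
writeFrameSequencePng <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(nFrames(seq))) {
    png::writePNG(seq@frames[, , t] / 255,
                  file.path(dir, sprintf("frame%02d.png", t)))
  }
  invisible(dir)
}
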