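## Lifespan-curve assembly and CSV input/output.

#' Assemble a lifespan curve from daily live counts
#'
#' Orders the counts by day and marks any day missing from the contiguous
#' day grid as censored (count carried as 0 but excluded from error
#' statistics).
#'
#' @param daily list of [LiveCount-class] for one plate.
#' @param n0 initial worm count placed on the plate.
#' @return A [LifespanCurve-class].
#' @export
assembleCurve <- function(daily, n0) {
  if (length(daily) == 0L)
    return(LifespanCurve(plateId = "plate", n0 = n0, days = integer(),
                         counts = integer(), censored = logical()))
  ids <- unique(vapply(daily, function(x) x@plateId, ""))
  if (length(ids) != 1L) stop("all LiveCounts must share one plate_id")
  days <- vapply(daily, function(x) x@day, 1L)
  if (anyDuplicated(days)) stop("duplicate day in daily counts")
  ord <- order(days)
  days <- days[ord]
  counts <- vapply(daily, liveTotal, 1L)[ord]
  grid <- seq(min(days), max(days))
  full <- integer(length(grid))
  cens <- !(grid %in% days)
  full[match(days, grid)] <- counts
  LifespanCurve(plateId = ids, n0 = n0, days = grid, counts = full,
                censored = cens)
}

#' Read lifespan curves from CSV
#'
#' Expects columns plate_id, day, count and optionally censored; one curve
#' per plate_id. Initial populations come from \code{n0Map}, a data.frame
#' with columns plate_id and n0 (or a named vector), defaulting to each
#' curve's maximum count.
#'
#' @param path CSV path.
#' @param n0Map plate_id -> n0 mapping (data.frame or named vector).
#' @return Named list of [LifespanCurve-class].
#' @export
readCurvesCsv <- function(path, n0Map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "day", "count")
  if (!all(need %in% names(df)))
    stop("curve CSV needs columns plate_id, day, count")
  if (!"censored" %in% names(df)) df$censored <- FALSE
  if (is.data.frame(n0Map))
    n0Map <- stats::setNames(n0Map$n0, n0Map$plate_id)
  out <- lapply(split(df, df$plate_id), function(d) {
    d <- d[order(d$day), ]
    n0 <- if (!is.null(n0Map) && d$plate_id[1] %in% names(n0Map))
      n0Map[[d$plate_id[1]]] else max(d$count)
    LifespanCurve(d$plate_id[1], n0, d$day, d$count, as.logical(d$censored))
  })
  out
}

#' Write lifespan curves to CSV
#'
#' @param curves a [LifespanCurve-class] or list of them.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeCurvesCsv <- function(curves, path) {
  if (is(curves, "LifespanCurve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pooled survival fraction across plates
#'
#' Sums per-plate counts on the union day grid and divides by the summed
#' initial populations; censored plate-days are excluded from both
#' numerator and denominator for their day.
#'
#' @param curves list of [LifespanCurve-class].
#' @return data.frame with columns day, alive, atRisk, fraction.
#' @export
survivalFraction <- function(curves) {
  days <- sort(unique(unlist(lapply(curves, curveDays))))
  alive <- atRisk <- numeric(length(days))
  for (cv in curves) {
    m <- match(cv@days, days)
    ok <- !cv@censored
    alive[m[ok]] <- alive[m[ok]] + cv@counts[ok]
    atRisk[m[ok]] <- atRisk[m[ok]] + cv@n0
  }
  data.frame(day = days, alive = alive, atRisk = atRisk,
             fraction = ifelse(atRisk > 0, alive / atRisk, NA_real_))
}
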