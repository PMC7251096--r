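## The adaptive two-period post-processing filter, manual-count regressive
## correction, error metrics and aggregation-probability estimation.

#' Cap a curve at its initial population
#'
#' A plate can never hold more live worms than were placed on it, so any
#' count exceeding n0 is clamped to n0. Idempotent.
#'
#' @param curve a [LifespanCurve-class].
#' @return The capped curve.
#' @export
capToInitial <- function(curve) {
  curve@counts <- pmin(curve@counts, curve@n0)
  curve
}

## position of the dividing day within the curve's day grid (last day
## <= m); errors if m lies outside the observed range.
dividingIndex <- function(curve, cfg) {
  m <- cfg@dividingDay
  if (length(curve@days) == 0L) return(0L)
  if (m < curve@days[1] || m > curve@days[length(curve@days)])
    stop("dividing day lies outside the curve's day range")
  max(which(curve@days <= m))
}

#' First-period correction: raise earlier counts
#'
#' In the first half of the assay, counting errors are dominated by worms
#' hiding in the wall shadow or aggregating (false negatives), so a day
#' that detects more worms than the previous day indicates the previous
#' count was too low. A backward pass over days up to the dividing day
#' raises each count to at least the next day's value. Days after the
#' dividing day are untouched, and no correction propagates from them: a
#' late-period rise is treated as contamination, never as evidence that
#' early counts were low.
#'
#' @param curve a capped [LifespanCurve-class].
#' @param cfg a [FilterConfig-class].
#' @return The corrected curve.
#' @export
filterFirstPeriod <- function(curve, cfg = FilterConfig()) {
  mi <- dividingIndex(curve, cfg)
  counts <- curve@counts
  if (mi >= 2L) {
    for (d in (mi - 1L):1L)
      counts[d] <- max(counts[d], counts[d + 1L])
  }
  curve@counts <- counts
  curve
}

#' Second-period correction: clamp later counts
#'
#' In the second half of the assay dirt has accumulated and survival is
#' low, so a rise in the count is a false positive. A forward pass from
#' the dividing day makes each count the ceiling of the next day's count.
#'
#' @param curve a capped [LifespanCurve-class].
#' @param cfg a [FilterConfig-class].
#' @return The corrected curve.
#' @export
filterSecondPeriod <- function(curve, cfg = FilterConfig()) {
  mi <- dividingIndex(curve, cfg)
  counts <- curve@counts
  if (mi >= 1L && mi < length(counts)) {
    for (d in mi:(length(counts) - 1L))
      counts[d + 1L] <- min(counts[d + 1L], counts[d])
  }
  curve@counts <- counts
  curve
}

#' Adaptive two-period curve filter
#'
#' Applies, in order: the n0 cap, the first-period backward raise, and the
#' second-period forward clamp. The composition yields a monotone
#' non-increasing curve bounded by [0, n0], leaves already-valid curves
#' unchanged, and is idempotent.
#'
#' @param curve a [LifespanCurve-class].
#' @param cfg a [FilterConfig-class]; the dividing day should be the
#'   strain's mean lifespan (N2: 14, daf-2: 42).
#' @return The filtered curve.
#' @examples
#' cv <- LifespanCurve("p", 10, 1:7, c(10, 9, 10, 8, 7, 8, 6))
#' curveCounts(adaptiveFilter(cv, FilterConfig(dividingDay = 4)))
#' @export
adaptiveFilter <- function(curve, cfg = FilterConfig()) {
  filterSecondPeriod(filterFirstPeriod(capToInitial(curve), cfg), cfg)
}

#' Regressive correction of a manual count
#'
#' Manual counts also miss worms hidden in the wall shadow. If a later
#' manual count is higher, the worm must have been present but hidden
#' earlier, so a full-range backward maximum pass (capped at n0) gives the
#' real-worm curve; the difference to the visible curve counts the hidden
#' worms per day.
#'
#' @param manual a [LifespanCurve-class] of visible manual counts.
#' @return List with \code{real} (corrected [LifespanCurve-class]) and
#'   \code{hidden} (integer per day).
#' @export
regressiveCorrectManual <- function(manual) {
  visible <- pmin(manual@counts, manual@n0)
  counts <- visible
  n <- length(counts)
  if (n >= 2L)
    for (d in (n - 1L):1L) counts[d] <- max(counts[d], counts[d + 1L])
  real <- manual
  real@counts <- counts
  list(real = real, hidden = counts - visible)
}

#' Error report: automated versus reference curves
#'
#' Per plate-day the error is E = automated - reference (individuals):
#' negative errors are undetected worms (false negatives), positive errors
#' detected contamination (false positives). The population-level error
#' per day is |sum of E over plates| / sum of n0, in percent; the curve
#' error is its mean over non-censored days. Per-plate statistics (mean,
#' standard deviation, zero-error fraction) are computed over all
#' non-censored plate-days.
#'
#' @param auto list of automated [LifespanCurve-class] (or one curve).
#' @param reference matching list of reference curves (same plates, same
#'   day grids).
#' @return List with \code{perDay} (data.frame day, E, populationErrorPct),
#'   \code{curveErrorPct}, \code{plateMean}, \code{plateSd},
#'   \code{zeroErrorProb}.
#' @export
errorReport <- function(auto, reference) {
  if (is(auto, "LifespanCurve")) auto <- list(auto)
  if (is(reference, "LifespanCurve")) reference <- list(reference)
  if (length(auto) != length(reference))
    stop("auto and reference must pair up")
  days <- auto[[1]]@days
  sumE <- numeric(length(days))
  sumN0 <- 0
  allE <- numeric(0)
  for (i in seq_along(auto)) {
    a <- auto[[i]]; r <- reference[[i]]
    if (!identical(a@days, r@days))
      stop("day grids of automated and reference curves differ")
    ok <- !(a@censored | r@censored)
    e <- a@counts - r@counts
    sumE[ok] <- sumE[ok] + e[ok]
    sumN0 <- sumN0 + a@n0
    allE <- c(allE, e[ok])
  }
  popPct <- abs(sumE) / sumN0 * 100
  okDay <- !vapply(seq_along(days), function(k)
    all(vapply(auto, function(a) a@censored[k], TRUE)), TRUE)
  list(perDay = data.frame(day = days, E = sumE,
                           populationErrorPct = popPct),
       curveErrorPct = mean(popPct[okDay]),
       plateMean = mean(allE),
       plateSd = stats::sd(allE),
       zeroErrorProb = mean(allE == 0))
}

#' Estimate worm aggregation probabilities from blob areas
#'
#' A collision of order k in one frame is a blob whose area indicates k
#' single-worm bodies. The single-worm band is [minArea, maxArea / 2] of
#' the worm model (the model maximum is the biggest two-worm aggregate);
#' a blob of area A is read as the smallest k with A <= k * maxSingle,
#' provided A >= k * minSingle. The probability of order-k aggregation is
#' the fraction of worm-frames involved: k times the number of order-k
#' collision blobs over (worms per plate x frames x plates).
#'
#' @param blobAreas list (one element per plate) of numeric vectors of all
#'   centre blob areas over all frames of that plate's sequence.
#' @param wormsPerPlate nominal worm count per plate (scalar or vector).
#' @param nFrames frames per sequence.
#' @param model a [WormModel-class].
#' @param orders aggregation orders to report.
#' @return data.frame with columns order and probability.
#' @export
estimateAggregation <- function(blobAreas, wormsPerPlate, nFrames = 30,
                                model = WormModel(), orders = 2:4) {
  if (length(wormsPerPlate) == 1L)
    wormsPerPlate <- rep(wormsPerPlate, length(blobAreas))
  minS <- model@minArea
  maxS <- model@maxArea / 2
  totalWormFrames <- sum(wormsPerPlate) * nFrames
  blobOrder <- function(a) {
    k <- ceiling(a / maxS)
    ifelse(a >= k * minS, k, 0L)
  }
  prob <- vapply(orders, function(k) {
    hits <- sum(vapply(blobAreas, function(a)
      sum(blobOrder(a) == k), 1))
    k * hits / totalWormFrames
  }, 1)
  data.frame(order = orders, probability = prob)
}

#' Corrupt a true curve with day-profiled count errors
#'
#' Fast count-level error injection for statistical tests of the filter,
#' bypassing image simulation. Each day independently subtracts
#' Binomial(alive, pFN(day)) missed worms and adds
#' Binomial(opportunities, pFP(day)) spurious detections. Typical assay
#' error profiles have false negatives near 20% per day early (hiding,
#' aggregation), decaying late, and false positives growing from about 3%
#' to about 12% as dirt accumulates.
#'
#' @param curve a true [LifespanCurve-class].
#' @param pFN,pFP numeric vectors (recycled) of per-day probabilities.
#' @param opportunities binomial size for false positives per day
#'   (defaults to n0: each dirt-prone site of a plate).
#' @return The corrupted curve.
#' @export
injectCountErrors <- function(curve, pFN, pFP,
                              opportunities = curve@n0) {
  n <- length(curve@days)
  pFN <- rep_len(pFN, n); pFP <- rep_len(pFP, n)
  if (any(pFN < 0 | pFN > 1 | pFP < 0 | pFP > 1))
    stop("error probabilities must be in [0, 1]")
  fn <- stats::rbinom(n, curve@counts, pFN)
  fp <- stats::rbinom(n, opportunities, pFP)
  curve@counts <- pmax(0L, curve@counts - fn) + fp
  curve
}

#' Default day profiles for count-error injection
#'
#' Piecewise-constant per-day probabilities matching the error structure
#' of plate assays: early false negatives start near 20% and decay towards
#' the dividing day; false positives are about 3% early and 12% late,
#' while late false negatives drop to about 2%.
#'
#' @param days integer day grid.
#' @param dividingDay boundary between the two periods.
#' @return List with numeric vectors \code{pFN} and \code{pFP}.
#' @export
defaultErrorProfiles <- function(days, dividingDay = 14) {
  early <- days <= dividingDay
  frac <- ifelse(early, pmax(0, (dividingDay - days) / dividingDay), 0)
  pFN <- ifelse(early, 0.02 + 0.18 * frac, 0.02)
  pFP <- ifelse(early, 0.03, 0.12)
  list(pFN = pFN, pFP = pFP)
}
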