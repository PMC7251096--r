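# Curve assembly, the adaptive two-period filter, reference correction,
# error metrics and aggregation estimation.

cv <- function(counts, n0 = 10, days = seq_along(counts))
  LifespanCurve("p", n0, days, counts)

test_that("curve assembly orders days and marks gaps censored", {
  lcs <- lapply(c(3, 1, 2, 5), function(d) LiveCount("p", d, 0L, 3L, 0L))
  curve <- assembleCurve(lcs, n0 = 10)
  expect_equal(curveDays(curve), 1:5)
  expect_equal(censored(curve), c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_error(assembleCurve(c(lcs, lcs[1]), 10), "duplicate")
  expect_length(curveDays(assembleCurve(list(), 10)), 0L)
})

test_that("counts are capped at the initial population, idempotently", {
  curve <- cv(c(11, 9, 12, 8))
  capped <- capToInitial(curve)
  expect_equal(curveCounts(capped), c(10, 9, 10, 8))
  expect_identical(curveCounts(capToInitial(capped)), curveCounts(capped))
  expect_identical(curveCounts(capToInitial(cv(c(9, 8)))), c(9L, 8L))
})

test_that("first-period correction raises counts backward to the divide", {
  f <- FilterConfig(dividingDay = 4)
  out <- filterFirstPeriod(cv(c(9, 8, 10, 10, 5, 6)), f)
  expect_equal(curveCounts(out), c(10, 10, 10, 10, 5, 6))
  mono <- cv(c(10, 9, 8, 7, 6, 5))
  expect_identical(curveCounts(filterFirstPeriod(mono, f)),
                   curveCounts(mono))
  ## a rise after the divide never propagates into the first period
  out2 <- filterFirstPeriod(cv(c(8, 7, 9), days = 1:3), FilterConfig(2))
  expect_equal(curveCounts(out2), c(8, 7, 9))
})

test_that("second-period correction clamps counts forward from the divide", {
  f <- FilterConfig(dividingDay = 3)
  out <- filterSecondPeriod(cv(c(9, 8, 7, 8, 6)), f)
  expect_equal(curveCounts(out), c(9, 8, 7, 7, 6))
  mono <- cv(c(9, 8, 7, 6, 5))
  expect_identical(curveCounts(filterSecondPeriod(mono, f)),
                   curveCounts(mono))
  spike <- filterSecondPeriod(cv(c(9, 8, 4, 4, 8, 3)), f)
  expect_equal(curveCounts(spike), c(9, 8, 4, 4, 4, 3))
})

test_that("the adaptive filter composes cap, raise and clamp", {
  out <- adaptiveFilter(cv(c(10, 9, 10, 8, 7, 8, 6)), FilterConfig(4))
  expect_equal(curveCounts(out), c(10, 10, 10, 8, 7, 7, 6))
  allFull <- cv(rep(10, 6))
  expect_identical(curveCounts(adaptiveFilter(allFull, FilterConfig(3))),
                   curveCounts(allFull))
  expect_error(adaptiveFilter(cv(c(5, 4)), FilterConfig(40)), "outside")
})

test_that("filter algebra: idempotent, monotone, bounded, identity", {
  set.seed(17)
  for (i in 1:300) {
    n0 <- sample(5:20, 1)
    nd <- sample(5:30, 1)
    counts <- pmax(0, sample(0:(n0 + 4), nd, replace = TRUE))
    curve <- cv(counts, n0 = n0, days = seq_len(nd))
    f <- FilterConfig(sample(seq_len(nd), 1))
    out <- adaptiveFilter(curve, f)
    oc <- curveCounts(out)
    expect_true(all(diff(oc) <= 0))
    expect_true(all(oc >= 0 & oc <= n0))
    expect_true(all(oc >= min(c(counts, 0)) & oc <= max(pmin(counts, n0))))
    expect_identical(curveCounts(adaptiveFilter(out, f)), oc)
    if (all(diff(counts) <= 0) && all(counts <= n0))
      expect_identical(oc, as.integer(counts))
  }
})

test_that("manual counts get a full-range regressive correction", {
  res <- regressiveCorrectManual(cv(c(10, 8, 9, 7)))
  expect_equal(curveCounts(res$real), c(10, 9, 9, 7))
  expect_equal(res$hidden, c(0, 1, 0, 0))
  mono <- regressiveCorrectManual(cv(c(9, 8, 7)))
  expect_true(all(mono$hidden == 0))
  set.seed(4)
  for (i in 1:50) {
    x <- cv(sample(0:12, 8, replace = TRUE))
    r <- regressiveCorrectManual(x)
    expect_true(all(curveCounts(r$real) >= pmin(curveCounts(x), 10)))
    expect_true(all(r$hidden >= 0))
  }
})

test_that("error reports follow E = automated - reference", {
  ref <- cv(c(10, 9, 8, 7))
  same <- errorReport(ref, ref)
  expect_true(all(same$perDay$E == 0))
  expect_equal(same$zeroErrorProb, 1)
  expect_equal(same$curveErrorPct, 0)
  ## ten plates of n0 = 10 (population 100); one +2 error on day 2
  refs <- lapply(1:10, function(i) cv(c(10, 9, 8, 7)))
  autos <- refs
  autos[[1]] <- cv(c(10, 11, 8, 7))
  rep2 <- errorReport(autos, refs)
  expect_equal(rep2$perDay$populationErrorPct[2], 2)
  expect_error(errorReport(cv(c(1, 2)), cv(c(1, 2), days = 3:4)), "differ")
})

test_that("aggregation probabilities follow the worm-frame formula", {
  m <- WormModel()   # single-worm band [20, 120]
  none <- estimateAggregation(list(rep(50, 40)), 10, nFrames = 30, model = m)
  expect_true(all(none$probability[none$order >= 2] == 0))
  one <- estimateAggregation(list(c(rep(50, 29), 200)), 10, nFrames = 30,
                             model = m)
  expect_equal(one$probability[one$order == 2], 2 / 300)
  expect_equal(one$probability[one$order == 3], 0)
})

test_that("aggregation probability grows with worm density", {
  model <- simWormModel(SimConfig())
  collect <- function(nw, pl) {
    dcfg <- SimConfig(nPlates = 1, nWorms = nw, nDays = 1,
                      nFramesPerDay = 30, hidingProb = 0, dirtRate = 0,
                      displacementSd = 0, rotationSd = 0,
                      flickerFraction = 0, seed = 100 * pl + nw)
    assay <- simulateAssay(dcfg)
    fs <- frameSequence(assay, 1, 0)
    st <- stackSignatures(fs)
    z <- detectZones(classifyPixels(st))
    unlist(lapply(seq_len(nFrames(fs)), function(t) {
      blobs <- extractCenterBlobs(matrix(st[, , t], nrow(centerMask(z))),
                                  frames(fs)[, , t], z, t)
      vapply(blobs, function(b) b@area, 1)
    }))
  }
  P2 <- vapply(c(10, 30, 60, 90), function(nw) {
    est <- estimateAggregation(list(collect(nw, 1), collect(nw, 2)), nw,
                               nFrames = 30, model = model)
    est$probability[est$order == 2]
  }, 1)
  expect_true(all(diff(P2[1:3]) >= 0))   # 10 -> 30 -> 60 worms
  expect_gt(P2[4], P2[1])                # crowded plates collide more
})

test_that("count-error injection matches its day profiles", {
  true <- cv(rep(10, 20), n0 = 10, days = 1:20)
  unchanged <- withr::with_seed(1, injectCountErrors(true, 0, 0))
  expect_identical(curveCounts(unchanged), curveCounts(true))
  wiped <- withr::with_seed(1, injectCountErrors(true, 1, 0))
  expect_true(all(curveCounts(wiped) == 0))
  expect_error(injectCountErrors(true, 1.2, 0), "probabilities")
  ## empirical corruption rates over many plate-days
  set.seed(8)
  nFn <- 0; nFp <- 0; N <- 4000
  for (i in seq_len(N / 20)) {
    out <- injectCountErrors(true, 0.2, 0.05)
    ## FN and FP mix per day; check the net expectation instead
    nFn <- nFn + sum(10 - pmin(curveCounts(out), 10))
  }
  ## E[net removed] per day = 10*0.2 - 10*0.05 truncated; loose band check
  expect_gt(nFn / N, 10 * 0.10)
  expect_lt(nFn / N, 10 * 0.20)
})

test_that("default error profiles decay FN and grow FP across the divide", {
  p <- defaultErrorProfiles(1:30, dividingDay = 14)
  expect_gt(p$pFN[1], 0.15)
  expect_lt(p$pFN[20], 0.03)
  expect_equal(p$pFP[1], 0.03)
  expect_equal(p$pFP[20], 0.12)
  expect_true(all(diff(p$pFN[1:14]) <= 0))
})

test_that("curve CSV round-trips and pools survival fractions", {
  tmp <- tempfile(fileext = ".csv")
  curves <- list(p1 = cv(c(10, 9, 8)), p2 = cv(c(9, 9, 7)))
  curves$p2@plateId <- "p2"
  writeCurvesCsv(curves, tmp)
  back <- readCurvesCsv(tmp, n0Map = c(p = 10, p2 = 10))
  expect_equal(length(back), 2L)
  expect_equal(curveCounts(back[[1]]), c(10, 9, 8))
  sf <- survivalFraction(curves)
  expect_equal(sf$fraction[1], 19 / 20)
})
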