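params0 <- detectionParams(oLow = 200, oUp = 240)

test_that("baseline is the median of in-bounds samples", {
  expect_equal(estimateBaseline(rep(220, 100),
                                detectionParams(oLow = 200, oUp = 250)), 220)
  set.seed(11)
  y <- rnorm(2e5, 220, 2)
  direct <- median(y[y > 200 & y < 240])
  expect_identical(estimateBaseline(y, params0), direct)
  expect_error(
    estimateBaseline(rep(300, 50), detectionParams(oLow = 200, oUp = 250)),
    "baseline error")
})

test_that("noise estimation: constant, Gaussian, short-trace and global mode", {
  expect_equal(estimateNoise(rep(220, 10), params0), 0)
  set.seed(12)
  y <- rnorm(1e6, 220, 2)
  expect_equal(estimateNoise(y, params0), 2, tolerance = 0.02)
  ## trace shorter than segmentSize: single short segment = plain sd
  y2 <- rnorm(5e3, 220, 2)
  inb <- y2[y2 > 200 & y2 < 240]
  expect_equal(estimateNoise(y2, params0), sd(inb))
  pg <- detectionParams(oLow = 200, oUp = 240, noiseMode = "global")
  expect_identical(estimateNoise(y2, pg), sd(inb))
  expect_error(estimateNoise(rep(300, 10), params0), "noise error")
})

test_that("detection threshold formula and its failure modes", {
  expect_equal(detectionThreshold(200, 5, 10), 150)
  expect_equal(detectionThreshold(200, 0, 10), 200)
  expect_equal(detectionThreshold(200, 5, 0), 200)
  expect_error(detectionThreshold(100, 15, 10), "configuration error")
})

test_that("candidate events are maximal below-threshold runs", {
  expect_equal(nrow(findCandidateEvents(rep(220, 1000), 200)), 0L)
  y <- rep(220, 1000)
  y[101:150] <- 20                      # 0-based [100, 150)
  cand <- findCandidateEvents(y, 200)
  expect_equal(cand$start, 100L)
  expect_equal(cand$end, 150L)
  expect_equal(cand$min_current, 20)
  expect_false(cand$truncated)
  ## runs touching the boundary are flagged truncated
  y2 <- rep(220, 100); y2[1:5] <- 20; y2[96:100] <- 20
  expect_true(all(findCandidateEvents(y2, 200)$truncated))
  ## adjacency: runs separated by a single above-threshold sample stay split
  y3 <- rep(220, 100); y3[11:20] <- 20; y3[22:31] <- 20
  expect_equal(nrow(findCandidateEvents(y3, 200)), 2L)
})

test_that("50 injected dips are recovered exactly against the truth", {
  inj <- injectEvents(2e5, 50, ratio = 0.1, tau = 40L, seed = 21)
  bl <- channelBaseline(inj$y, params0)
  cand <- findCandidateEvents(inj$y, bl@bAll)
  expect_equal(nrow(cand), 50L)
  expect_equal(cand$start, inj$truth$start)
  expect_equal(cand$end, inj$truth$end)
})

test_that("dwell-time and ratio filters respect the configured windows", {
  mk <- function(tau, min_c) data.frame(start = 100L, end = 100L + tau,
                                        min_current = min_c,
                                        mean_current = min_c,
                                        truncated = FALSE)
  ## tau = 3 rejected, tau = 4 accepted with the assay's inclusive settings
  expect_equal(nrow(filterEvents(mk(3L, 22), 220, params0)), 0L)
  expect_equal(nrow(filterEvents(mk(4L, 22), 220, params0)), 1L)
  ## strict mode excludes the boundary
  ps <- detectionParams(oLow = 200, oUp = 240, inclusiveBounds = FALSE)
  expect_equal(nrow(filterEvents(mk(4L, 22), 220, ps)), 0L)
  expect_equal(nrow(filterEvents(mk(5L, 22), 220, ps)), 1L)
  ## ratio window: 0.60 > bMax = 0.55 rejected; boundary 0.55 accepted
  expect_equal(nrow(filterEvents(mk(50L, 0.60 * 220), 220, params0)), 0L)
  expect_equal(nrow(filterEvents(mk(50L, 0.55 * 220), 220, params0)), 1L)
  ## truncated candidates are dropped; empty input passes through
  tr <- mk(50L, 22); tr$truncated <- TRUE
  expect_equal(nrow(filterEvents(tr, 220, params0)), 0L)
  expect_equal(nrow(filterEvents(mk(4L, 22)[0, ], 220, params0)), 0L)
})

test_that("full pipeline: noise-only yields nothing, blocked pore fails QC", {
  set.seed(31)
  tab <- detectEvents(nanoporeTrace(rnorm(2e5, 220, 2)), params0)
  expect_equal(nEvents(tab), 0L)
  expect_true(baselines(tab)$qc_pass)
  zero <- detectEvents(nanoporeTrace(rep(0, 1e4)), params0)
  expect_false(baselines(zero)$qc_pass)
  expect_equal(nEvents(zero), 0L)
  expect_error(detectEvents(nanoporeTrace(numeric())), "non-empty")
})

test_that("pipeline recovers injected events with exact boundaries", {
  inj <- injectEvents(3e5, 100, ratio = 0.1, tau = 50L, seed = 41)
  tab <- detectEvents(nanoporeTrace(inj$y), params0)
  ev <- events(tab)
  expect_equal(nrow(ev), 100L)
  expect_true(all(abs(ev$start - inj$truth$start) <= 1L))
  expect_true(all(abs(ev$end - inj$truth$end) <= 1L))
  expect_true(all(ev$ratio < 0.15))
  expect_equal(ev$tau, ev$end - ev$start)
})

test_that("pipeline output equals the naive single-pass reference", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 2e4
    y <- rnorm(n, 220, 2)
    k <- sample(5:20, 1)
    inj <- injectEvents(n, k, ratio = runif(1, 0.05, 0.45),
                        tau = sample(c(3L, 4L, 30L, 200L, 320L), 1),
                        seed = seed + 100)
    y <- inj$y
    ref <- naiveDetect(y, 200, 240)
    got <- events(detectEvents(nanoporeTrace(y), params0))
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$end, ref$end)
      expect_equal(got$ratio, ref$ratio, tolerance = 1e-12)
    }
  }
})

test_that("detection is scale-equivariant", {
  inj <- injectEvents(5e4, 20, ratio = 0.2, tau = 30L, seed = 51)
  base <- events(detectEvents(nanoporeTrace(inj$y), params0))
  for (c_ in c(0.5, 3, 10)) {
    sc <- events(detectEvents(
      nanoporeTrace(inj$y * c_),
      detectionParams(oLow = 200 * c_, oUp = 240 * c_)))
    expect_equal(sc$start, base$start)
    expect_equal(sc$end, base$end)
    expect_equal(sc$ratio, base$ratio, tolerance = 1e-9)
  }
})

test_that("enlarging the filter windows never loses events", {
  inj <- injectEvents(1e5, 40, ratio = 0.3, tau = 20L, seed = 61)
  set.seed(62)
  extra <- injectEvents(1e5, 15, ratio = 0.5, tau = 350L, seed = 63)$y
  for (y in list(inj$y, extra)) {
    counts <- sapply(list(
      detectionParams(oLow = 200, oUp = 240, tMin = 10L, tMax = 100L,
                      bMin = 0.1, bMax = 0.35),
      detectionParams(oLow = 200, oUp = 240, tMin = 4L, tMax = 300L,
                      bMin = 0.05, bMax = 0.45),
      detectionParams(oLow = 200, oUp = 240, tMin = 2L, tMax = 500L,
                      bMin = 0, bMax = 0.55)
    ), function(p) nEvents(detectEvents(nanoporeTrace(y), p)))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("unstable per-segment noise is flagged", {
  set.seed(71)
  quiet <- rnorm(5e4, 220, 1)
  loud <- rnorm(5e4, 220, 6)
  p <- detectionParams(oLow = 180, oUp = 260, segmentSize = 5e4,
                       qcSdFactor = 3)
  bl <- channelBaseline(c(quiet, loud), p)
  expect_false(bl@qcStable)
  bl2 <- channelBaseline(c(quiet, rnorm(5e4, 220, 1.2)), p)
  expect_true(bl2@qcStable)
})

test_that("multi-channel runs record failures instead of raising", {
  set.seed(81)
  traces <- list(nanoporeTrace(rnorm(2e4, 220, 2), channelId = 1L),
                 nanoporeTrace(rep(0, 1e4), channelId = 2L))
  tab <- detectExperiment(traces, params0)
  bl <- baselines(tab)
  expect_equal(bl$qc_pass, c(TRUE, FALSE))
  expect_equal(nrow(bl), 2L)
})
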