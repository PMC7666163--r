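probeOnly <- function(rate = 0.056) {
  defaultSpecies("probe")[1, ] |>
    transform(event_rate_hz = rate)
}

test_that("simulation is deterministic given seed and channel", {
  cfg <- simConfig(nChannels = 2, durationS = 5, seed = 17)
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(lapply(a$traces, samples), lapply(b$traces, samples))
  expect_identical(a$truth, b$truth)
  expect_identical(a$outlierChannels, b$outlierChannels)
  ## different channels differ
  expect_false(identical(samples(a$traces[[1]]), samples(a$traces[[2]])))
})

test_that("zero rates give pure noise and an empty truth table", {
  sp <- probeOnly(rate = 0)
  cfg <- simConfig(nChannels = 1, durationS = 5, species = sp, seed = 2,
                   outlierFraction = 0)
  sim <- simulateChannel(cfg, 1L)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(length(sim$trace), round(5 * 3012))
  expect_equal(mean(samples(sim$trace)), 220, tolerance = 0.1)
})

test_that("injected event counts follow the Poisson mean", {
  rate <- 0.5; dur <- 60
  cfg0 <- simConfig(nChannels = 1, durationS = dur,
                    species = probeOnly(rate), outlierFraction = 0, seed = 1)
  counts <- sapply(1:10, function(s) {
    cfg <- simConfig(nChannels = 1, durationS = dur,
                     species = probeOnly(rate), outlierFraction = 0,
                     seed = s)
    nrow(simulateChannel(cfg, 1L)$truth)
  })
  m <- rate * dur
  expect_true(all(abs(counts - m) <= 4 * sqrt(m)))
})

test_that("planted events stay within bounds and never overlap", {
  cfg <- simConfig(nChannels = 3, durationS = 30, seed = 23,
                   species = rbind(probeOnly(0.3), defaultSpecies("buffer")))
  sim <- simulateExperiment(cfg)
  n <- length(sim$traces[[1]])
  for (ch in 1:3) {
    tt <- sim$truth[sim$truth$channel == ch, ]
    tt <- tt[order(tt$start), ]
    expect_true(all(tt$start >= 1L))
    expect_true(all(tt$end <= n - 1L))
    if (nrow(tt) > 1)
      expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  }
})

test_that("a probe run's histogram peaks at the published modal ratio", {
  cfg <- simConfig(nChannels = 4, durationS = 60, seed = 29,
                   species = probeOnly(0.2), outlierFraction = 0)
  sim <- simulateExperiment(cfg)
  det <- detectExperiment(sim$traces, detectionParams())
  s <- summarizeExperiment(det)
  ## argmax bin [0.10, 0.15) contains 0.10
  expect_equal(modeRatio(s), 0.125)
})

test_that("outlier planting: rounding rule and flagged-set recovery", {
  cfg512 <- simConfig(nChannels = 512, durationS = 1, seed = 3)
  expect_equal(length(plannedOutlierChannels(cfg512)), 13L)  # round(12.8)
  cfg0 <- simConfig(nChannels = 10, durationS = 1, seed = 3,
                    outlierFraction = 0)
  expect_equal(length(plannedOutlierChannels(cfg0)), 0L)

  ## flagged set equals the planted set on a 40-channel run
  cfg <- simConfig(nChannels = 40, durationS = 120, seed = 31,
                   species = probeOnly(0.056), outlierFraction = 0.025,
                   outlierRateFactor = 10)
  sim <- simulateExperiment(cfg)
  det <- detectExperiment(sim$traces, detectionParams())
  s <- summarizeExperiment(det, outlierFactor = 5)
  expect_equal(outlierChannels(s), sim$outlierChannels)
})

test_that("detector recall and precision on planted events reach 0.99", {
  sp <- speciesProfile("probe", eventRateHz = 0.5, ratioCenter = 0.2,
                       ratioSpread = 0.04, tauLogMean = log(40),
                       tauLogSd = 0.35)
  tp <- 0L; fn <- 0L; det_n <- 0L; matched_det <- 0L
  for (seed in 1:6) {
    cfg <- simConfig(nChannels = 1, durationS = 60, species = sp,
                     outlierFraction = 0, seed = seed)
    sim <- simulateChannel(cfg, 1L)
    det <- events(detectEvents(sim$trace, detectionParams()))
    tt <- sim$truth[sim$truth$ratio <= 0.4 &
                      sim$truth$tau >= 10 & sim$truth$tau <= 200, ]
    hit <- vapply(seq_len(nrow(tt)), function(i)
      any(det$start < tt$end[i] & det$end > tt$start[i]), logical(1))
    tp <- tp + sum(hit); fn <- fn + sum(!hit)
    det_n <- det_n + nrow(det)
    matched_det <- matched_det + sum(vapply(seq_len(nrow(det)), function(i)
      any(sim$truth$start < det$end[i] & sim$truth$end > det$start[i]),
      logical(1)))
  }
  expect_gte(tp / (tp + fn), 0.99)
  expect_gte(matched_det / det_n, 0.99)
})

test_that("voltage gating silences gated species below their threshold", {
  sp <- probeOnly(0.3)   # gate at 200 mV magnitude
  lo <- simConfig(nChannels = 1, durationS = 60, species = sp,
                  voltageMv = -180, outlierFraction = 0, seed = 5)
  hi <- simConfig(nChannels = 1, durationS = 60, species = sp,
                  voltageMv = -220, outlierFraction = 0, seed = 5)
  sim_lo <- simulateChannel(lo, 1L)
  sim_hi <- simulateChannel(hi, 1L)
  expect_equal(nrow(sim_lo$truth), 0L)
  expect_gt(nrow(sim_hi$truth), 10)
  det_lo <- nEvents(detectEvents(sim_lo$trace, detectionParams()))
  expect_equal(det_lo, 0L)
})

test_that("sub-resolution intact oligos add little over buffer background", {
  buffer <- defaultSpecies("buffer")
  intact <- defaultSpecies(c("intact_oligo", "buffer"))
  tot <- function(species, seed) {
    cfg <- simConfig(nChannels = 4, durationS = 240, species = species,
                     outlierFraction = 0, seed = seed)
    sim <- simulateExperiment(cfg)
    nEvents(detectExperiment(sim$traces, detectionParams()))
  }
  b <- sum(sapply(1:10, function(s) tot(buffer, 1000 + s)))
  i <- sum(sapply(1:10, function(s) tot(intact, 2000 + s)))
  expect_lte(i, 2 * max(b, 1))
  expect_lte(b, 2 * max(i, 1))
})

test_that("infeasible packing raises a simulation error", {
  sp <- speciesProfile("probe", eventRateHz = 50, ratioCenter = 0.1,
                       tauLogMean = log(500), tauLogSd = 0.1)
  cfg <- simConfig(nChannels = 1, durationS = 1, species = sp,
                   outlierFraction = 0, seed = 1)
  expect_error(simulateChannel(cfg, 1L), "simulation error")
})
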