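#' @include accessors.R
NULL

#' Construct detection parameters
#'
#' @param oLow,oUp open-pore current bounds in pA, or `NA` to estimate them
#'   per trace (mode of a 1-pA histogram of the samples, plus/minus 25 times
#'   a robust noise scale taken from the central 50% of samples).
#' @param kSigma threshold multiplier; the detection threshold is
#'   `b_o - kSigma * sigma_o`. Default 10.
#' @param segmentSize samples per segment for local baseline/noise
#'   estimation. Default 100000.
#' @param tMin,tMax dwell-time window, data time points. Defaults 4 and 300.
#' @param bMin,bMax window on `min(I_r)/b_o`. Defaults 0 and 0.55.
#' @param inclusiveBounds closed (`<=`, default) or open (`<`) filter windows.
#' @param noiseMode `"median"` (default) or `"global"`; see
#'   [DetectionParams-class].
#' @param baselineMode `"segment"` (default) or `"global"`.
#' @param qcSdFactor unstable-baseline flag threshold on the max/min ratio of
#'   per-segment noise. Default 3.
#' @return A [DetectionParams-class] object.
#' @examples
#' detectionParams(oLow = 180, oUp = 260)
#' @export
detectionParams <- function(oLow = NA_real_, oUp = NA_real_, kSigma = 10,
                            segmentSize = 100000L, tMin = 4L, tMax = 300L,
                            bMin = 0, bMax = 0.55, inclusiveBounds = TRUE,
                            noiseMode = c("median", "global"),
                            baselineMode = c("segment", "global"),
                            qcSdFactor = 3) {
  new("DetectionParams",
      oLow = as.numeric(oLow), oUp = as.numeric(oUp),
      kSigma = as.numeric(kSigma), segmentSize = as.integer(segmentSize),
      tMin = as.integer(tMin), tMax = as.integer(tMax),
      bMin = as.numeric(bMin), bMax = as.numeric(bMax),
      inclusiveBounds = isTRUE(inclusiveBounds),
      noiseMode = match.arg(noiseMode),
      baselineMode = match.arg(baselineMode),
      qcSdFactor = as.numeric(qcSdFactor))
}

#' Construct a trace object
#'
#' @param samples numeric vector of current samples, pA.
#' @param channelId channel number.
#' @param samplingRateHz sampling rate, Hz. Default 3012.
#' @param voltageMv applied potential, mV (negative by device convention).
#' @param source free-text provenance label.
#' @return A [NanoporeTrace-class].
#' @examples
#' tr <- nanoporeTrace(rnorm(1000, 220, 2), channelId = 7L)
#' @export
nanoporeTrace <- function(samples, channelId = 1L, samplingRateHz = 3012,
                          voltageMv = -210, source = "memory") {
  new("NanoporeTrace", channelId = as.integer(channelId),
      samples = as.numeric(samples),
      samplingRateHz = as.numeric(samplingRateHz),
      voltageMv = as.numeric(voltageMv), source = as.character(source))
}

## internal: resolve a trace argument to a numeric sample vector
.traceSamples <- function(trace) {
  if (is(trace, "NanoporeTrace")) trace@samples else as.numeric(trace)
}

#' Estimate open-pore current bounds from a trace
#'
#' Used when `oLow`/`oUp` are not supplied: the open-pore level is taken as
#' the mode of a 1-pA histogram of the samples, and the bounds as that mode
#' plus/minus 25 times a robust noise scale (the standard deviation of the
#' central 50% of samples, floored at 0.1 pA so constant traces remain
#' in-bounds).
#'
#' @param trace a [NanoporeTrace-class] or numeric vector.
#' @return Numeric of length 2: `c(oLow, oUp)`.
#' @export
estimateOpenPoreBounds <- function(trace) {
  y <- .traceSamples(trace)
  if (!length(y)) stop("cannot estimate bounds from an empty trace")
  bins <- floor(y)
  tab <- table(bins)
  mode_pa <- as.numeric(names(tab)[which.max(tab)]) + 0.5
  q <- stats::quantile(y, c(0.25, 0.75), names = FALSE)
  central <- y[y >= q[1] & y <= q[2]]
  sigma_rough <- if (length(central) > 1) stats::sd(central) else 0
  sigma_rough <- max(sigma_rough, 0.1)
  c(mode_pa - 25 * sigma_rough, mode_pa + 25 * sigma_rough)
}

.resolveBounds <- function(trace, params) {
  if (is.na(params@oLow) || is.na(params@oUp)) estimateOpenPoreBounds(trace)
  else c(params@oLow, params@oUp)
}

#' Estimate the open-pore baseline current
#'
#' The baseline `b_o` is the median of all samples strictly inside the
#' open-current window `(oLow, oUp)`.
#'
#' @inheritParams estimateOpenPoreBounds
#' @param params a [DetectionParams-class]; only the bounds are used.
#' @return `b_o` in pA.
#' @examples
#' estimateBaseline(rep(220, 100), detectionParams(oLow = 200, oUp = 250))
#' @export
estimateBaseline <- function(trace, params = detectionParams()) {
  y <- .traceSamples(trace)
  if (!length(y)) stop("baseline error: empty trace")
  b <- .resolveBounds(y, params)
  inb <- y[y > b[1] & y < b[2]]
  if (!length(inb))
    stop(sprintf(
      "baseline error: no samples inside (%.3g, %.3g); blocked/dead pore or wrong bounds",
      b[1], b[2]))
  stats::median(inb)
}

## per-segment 0-based half-open spans covering 1..n
.segmentSpans <- function(n, segmentSize) {
  starts <- seq.int(0L, n - 1L, by = segmentSize)
  data.frame(start = starts, end = pmin(starts + segmentSize, n))
}

## per-segment baseline/noise/threshold; returns data.frame with NA rows for
## segments lacking in-bounds samples
.segmentStats <- function(y, bounds, segmentSize, kSigma) {
  spans <- .segmentSpans(length(y), segmentSize)
  stats_ <- lapply(seq_len(nrow(spans)), function(i) {
    seg <- y[(spans$start[i] + 1L):spans$end[i]]
    inb <- seg[seg > bounds[1] & seg < bounds[2]]
    b_o <- if (length(inb)) stats::median(inb) else NA_real_
    s_o <- if (length(inb) >= 2) stats::sd(inb) else NA_real_
    c(b_o = b_o, sigma_o = s_o, n_inbounds = length(inb))
  })
  m <- do.call(rbind, stats_)
  out <- cbind(spans, as.data.frame(m))
  out$b_all <- out$b_o - kSigma * out$sigma_o
  out
}

#' Estimate the open-pore noise
#'
#' The trace is split into consecutive segments of `segmentSize` samples (the
#' last segment may be short); within each segment the standard deviation of
#' the in-bounds samples is computed. With `noiseMode = "median"` (default)
#' `sigma_o` is the median of the per-segment values, which is robust to
#' event-dense segments; with `noiseMode = "global"` it is the single
#' standard deviation of all in-bounds samples.
#'
#' @inheritParams estimateBaseline
#' @return `sigma_o` in pA (>= 0).
#' @export
estimateNoise <- function(trace, params = detectionParams()) {
  y <- .traceSamples(trace)
  b <- .resolveBounds(y, params)
  inb <- y[y > b[1] & y < b[2]]
  if (length(inb) < 2)
    stop("noise error: fewer than 2 in-bounds samples")
  if (params@noiseMode == "global") return(stats::sd(inb))
  seg <- .segmentStats(y, b, params@segmentSize, params@kSigma)
  sds <- seg$sigma_o[!is.na(seg$sigma_o)]
  if (!length(sds)) stats::sd(inb) else stats::median(sds)
}

#' Detection threshold below the baseline
#'
#' `b_all = b_o * (1 - kSigma * sigma_o / b_o) = b_o - kSigma * sigma_o`.
#'
#' @param bO open-pore baseline, pA (> 0).
#' @param sigmaO open-pore noise, pA (>= 0).
#' @param kSigma threshold multiplier, default 10.
#' @return `b_all` in pA.
#' @examples
#' detectionThreshold(200, 5, 10)  # 150
#' @export
detectionThreshold <- function(bO, sigmaO, kSigma = 10) {
  stopifnot(bO > 0, sigmaO >= 0, kSigma >= 0)
  b_all <- bO - kSigma * sigmaO
  if (b_all <= 0)
    stop(sprintf(
      "configuration error: threshold b_all = %.3g is not above zero current",
      b_all))
  b_all
}

## maximal runs of y < thr (thr scalar or per-sample vector);
## returns 0-based half-open candidate spans
.findRuns <- function(y, thr) {
  below <- y < thr
  if (!any(below))
    return(data.frame(start = integer(), end = integer(),
                      min_current = numeric(), mean_current = numeric(),
                      truncated = logical()))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s1 <- starts[keep]; e1 <- ends[keep]
  mins <- vapply(seq_along(s1),
                 function(i) min(y[s1[i]:e1[i]]), numeric(1))
  means <- vapply(seq_along(s1),
                  function(i) mean(y[s1[i]:e1[i]]), numeric(1))
  data.frame(start = s1 - 1L, end = e1,
             min_current = mins, mean_current = means,
             truncated = (s1 == 1L) | (e1 == length(y)))
}

#' Find candidate events below a threshold
#'
#' Candidates are maximal runs of consecutive samples whose value is strictly
#' below `bAll`, reported as 0-based half-open `[start, end)` spans with the
#' in-run minimum and mean current. Runs touching the first or last sample of
#' the trace are reported but flagged `truncated` (their true duration and
#' minimum are unknown) and are dropped by [filterEvents()].
#'
#' @inheritParams estimateOpenPoreBounds
#' @param bAll detection threshold, pA (scalar, or one value per sample for
#'   segment-local thresholds).
#' @return data.frame with columns `start`, `end`, `min_current`,
#'   `mean_current`, `truncated`.
#' @export
findCandidateEvents <- function(trace, bAll) {
  y <- .traceSamples(trace)
  stopifnot(length(bAll) == 1L || length(bAll) == length(y))
  .findRuns(y, bAll)
}

## dwell-time + ratio filter over a candidate data.frame carrying its own
## per-candidate baseline column i_o
.applyFilters <- function(cand, params) {
  if (!nrow(cand)) return(cand[0, , drop = FALSE])
  cand <- cand[!cand$truncated, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  tau <- cand$end - cand$start
  ratio <- cand$min_current / cand$i_o
  ok <- if (params@inclusiveBounds)
    tau >= params@tMin & tau <= params@tMax &
      ratio >= params@bMin & ratio <= params@bMax
  else
    tau > params@tMin & tau < params@tMax &
      ratio > params@bMin & ratio < params@bMax
  cand[ok, , drop = FALSE]
}

#' Filter candidate events on dwell time and residual-current ratio
#'
#' A candidate is kept iff `tMin <= tau <= tMax` and
#' `bMin <= min_current / b_o <= bMax` (with `<` instead of `<=` when
#' `inclusiveBounds = FALSE`). Boundary-truncated candidates are dropped.
#'
#' @param candidates data.frame as returned by [findCandidateEvents()].
#' @param baseline the channel baseline: a [ChannelBaseline-class] or a
#'   single `b_o` value in pA.
#' @param params a [DetectionParams-class].
#' @return data.frame of accepted events with columns `i_o`, `i_r`, `i_mean`,
#'   `ratio`, `start`, `end`, `tau`.
#' @export
filterEvents <- function(candidates, baseline, params = detectionParams()) {
  b_o <- if (is(baseline, "ChannelBaseline")) baseline@bO else
    as.numeric(baseline)
  stopifnot(is.finite(b_o), b_o > 0)
  cand <- candidates
  if (is.null(cand$i_o)) cand$i_o <- rep(b_o, nrow(cand))
  acc <- .applyFilters(cand, params)
  data.frame(
    i_o = acc$i_o, i_r = acc$min_current, i_mean = acc$mean_current,
    ratio = acc$min_current / acc$i_o,
    start = as.integer(acc$start), end = as.integer(acc$end),
    tau = as.integer(acc$end - acc$start)
  )
}

#' Per-channel baseline summary
#'
#' Runs baseline, noise and threshold estimation for one trace and reports
#' the result together with per-segment statistics and quality flags. Failed
#' estimation (no in-bounds samples) yields `qcPass = FALSE` rather than an
#' error, so multi-channel runs can record blocked pores.
#'
#' @inheritParams estimateBaseline
#' @return A [ChannelBaseline-class].
#' @export
channelBaseline <- function(trace, params = detectionParams()) {
  y <- .traceSamples(trace)
  ch <- if (is(trace, "NanoporeTrace")) trace@channelId else 1L
  b <- tryCatch(.resolveBounds(y, params), error = function(e) c(NA, NA))
  inb <- if (anyNA(b)) numeric() else y[y > b[1] & y < b[2]]
  if (length(inb) < 2)
    return(new("ChannelBaseline", channelId = ch, nInbounds = length(inb),
               qcPass = FALSE))
  seg_size <- if (params@baselineMode == "global") length(y) else
    params@segmentSize
  seg <- .segmentStats(y, b, seg_size, params@kSigma)
  b_o <- stats::median(inb)
  sds <- seg$sigma_o[!is.na(seg$sigma_o)]
  sigma_o <- if (params@noiseMode == "global" || !length(sds))
    stats::sd(inb) else stats::median(sds)
  b_all <- b_o - params@kSigma * sigma_o
  stable <- TRUE
  if (length(sds) >= 2 && max(sds) > 0) {
    lo <- min(sds)
    stable <- if (lo <= 0) FALSE else (max(sds) / lo) <= params@qcSdFactor
  }
  new("ChannelBaseline", channelId = ch, bO = b_o, sigmaO = sigma_o,
      bAll = b_all, nInbounds = length(inb), qcPass = TRUE,
      qcStable = stable, segments = seg)
}

.emptyEvents <- function() {
  data.frame(channel = integer(), i_o = numeric(), i_r = numeric(),
             i_mean = numeric(), ratio = numeric(), start = integer(),
             end = integer(), tau = integer())
}

.baselineRow <- function(bl) {
  data.frame(channel = bl@channelId, b_o = bl@bO, sigma_o = bl@sigmaO,
             b_all = bl@bAll, n_inbounds = bl@nInbounds,
             qc_pass = bl@qcPass, qc_stable = bl@qcStable)
}

#' Detect translocation events in one trace
#'
#' The full pipeline: baseline estimation, segmented noise estimation,
#' thresholding, candidate identification and feature filtering. With the
#' default `baselineMode = "segment"`, the baseline and detection threshold
#' are recomputed for every segment of `segmentSize` samples and candidates
#' are scored against their local values (the threshold is a per-sample step
#' function, so an event crossing a segment boundary is not split); each
#' accepted event reports the baseline of the segment containing its start.
#' Channels failing baseline/noise estimation (e.g. a blocked pore with all
#' samples out of bounds) yield `qc_pass = FALSE` and zero events rather
#' than an error.
#'
#' @param trace a [NanoporeTrace-class] (or numeric vector).
#' @param params a [DetectionParams-class].
#' @return An [EventTable-class] for the single channel.
#' @examples
#' set.seed(1)
#' y <- rnorm(20000, 220, 2)
#' y[5001:5060] <- rnorm(60, 22, 2)   # one deep 60-point blockade
#' tab <- detectEvents(nanoporeTrace(y), detectionParams(oLow = 200, oUp = 240))
#' events(tab)
#' @export
detectEvents <- function(trace, params = detectionParams()) {
  if (is(trace, "NanoporeTrace") && !length(trace@samples))
    stop("trace must be non-empty")
  y <- .traceSamples(trace)
  ch <- if (is(trace, "NanoporeTrace")) trace@channelId else 1L
  bl <- channelBaseline(trace, params)
  if (!bl@qcPass) {
    return(new("EventTable", events = .emptyEvents(),
               baselines = .baselineRow(bl), params = params))
  }
  if (bl@bAll <= 0)
    stop(sprintf(
      "configuration error: threshold b_all = %.3g is not above zero current",
      bl@bAll))
  seg <- bl@segments
  ## per-sample threshold and per-sample local baseline (step functions);
  ## segments without estimates inherit the channel-level values
  thr <- rep(bl@bAll, length(y))
  io <- rep(bl@bO, length(y))
  for (i in seq_len(nrow(seg))) {
    idx <- (seg$start[i] + 1L):seg$end[i]
    if (!is.na(seg$b_all[i])) thr[idx] <- seg$b_all[i]
    if (!is.na(seg$b_o[i])) io[idx] <- seg$b_o[i]
  }
  cand <- .findRuns(y, thr)
  cand$i_o <- io[cand$start + 1L]
  acc <- .applyFilters(cand, params)
  ev <- if (nrow(acc)) data.frame(
    channel = ch, i_o = acc$i_o, i_r = acc$min_current,
    i_mean = acc$mean_current, ratio = acc$min_current / acc$i_o,
    start = as.integer(acc$start), end = as.integer(acc$end),
    tau = as.integer(acc$end - acc$start)
  ) else .emptyEvents()
  new("EventTable", events = ev, baselines = .baselineRow(bl),
      params = params)
}

#' Detect events across a collection of traces
#'
#' Runs [detectEvents()] per channel; per-channel estimation failures are
#' recorded in the baseline table (`qc_pass = FALSE`), not raised.
#'
#' @param traces list of [NanoporeTrace-class] objects.
#' @param params a [DetectionParams-class].
#' @return A combined [EventTable-class].
#' @export
detectExperiment <- function(traces, params = detectionParams()) {
  stopifnot(length(traces) >= 1)
  tabs <- lapply(traces, detectEvents, params = params)
  new("EventTable",
      events = do.call(rbind, lapply(tabs, function(t) t@events)),
      baselines = do.call(rbind, lapply(tabs, function(t) t@baselines)),
      params = params)
}
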