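#' @include detection.R
NULL

#' Histogram of event counts over fractional residual current
#'
#' Bins accepted events by their `I_r/I_o` ratio with the assay's standard
#' 0.05 bin. Bins are left-closed right-open and tile `[0, upper]`; the last
#' bin is closed on the right so a ratio exactly at the upper filter bound is
#' counted.
#'
#' @param events an [EventTable-class], or a numeric vector of ratios.
#' @param binWidth bin size, default 0.05.
#' @param upper upper edge of the binned range; defaults to the `bMax` of the
#'   event table's parameters (0.55 for a plain ratio vector).
#' @return A [RatioHistogram-class].
#' @examples
#' h <- ratioHistogram(c(0.12, 0.13, 0.31))
#' binCounts(h)[binMids(h) == 0.125]  # 2
#' @export
ratioHistogram <- function(events, binWidth = 0.05, upper = NULL) {
  stopifnot(binWidth > 0)
  ratios <- if (is(events, "EventTable")) {
    if (is.null(upper)) upper <- events@params@bMax
    events@events$ratio
  } else as.numeric(events)
  if (is.null(upper)) upper <- 0.55
  breaks <- seq(0, upper + binWidth / 2, by = binWidth)
  if (breaks[length(breaks)] < upper) breaks <- c(breaks, upper)
  nbin <- length(breaks) - 1L
  idx <- findInterval(ratios, breaks, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= nbin]
  counts <- tabulate(idx, nbins = nbin)
  new("RatioHistogram", binWidth = binWidth, breaks = breaks,
      mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
      counts = as.integer(counts), total = sum(as.integer(counts)))
}

#' Summarize an experiment: per-channel counts, outliers, modal ratio
#'
#' A channel is flagged as an outlier when its accepted-event count exceeds
#' `outlierFactor` times the median nonzero per-channel count; working pores
#' in this assay typically agree within a factor of 5, while roughly 2.5%
#' record markedly higher counts. Outliers are flagged but remain included
#' in all totals. The modal ratio `(I_r/I_o)_max` is the midpoint of the
#' histogram bin with maximal count (ties resolve to the lowest bin).
#'
#' @param events an [EventTable-class].
#' @param outlierFactor must be > 1; default 5.
#' @param binWidth histogram bin for the modal ratio, default 0.05.
#' @return An [ExperimentSummary-class].
#' @export
summarizeExperiment <- function(events, outlierFactor = 5, binWidth = 0.05) {
  stopifnot(is(events, "EventTable"), outlierFactor > 1)
  chans <- sort(unique(c(events@baselines$channel, events@events$channel)))
  cnt <- vapply(chans, function(ch)
    sum(events@events$channel == ch), integer(1))
  names(cnt) <- chans
  nz <- cnt[cnt > 0L]
  out <- integer()
  if (length(nz)) {
    med <- stats::median(as.numeric(nz))
    out <- as.integer(names(cnt)[cnt > outlierFactor * med])
  }
  h <- ratioHistogram(events, binWidth = binWidth)
  mode_ratio <- if (h@total > 0L) h@mids[which.max(h@counts)] else NA_real_
  new("ExperimentSummary",
      perChannelCounts = cnt, totalCounts = sum(cnt),
      outlierChannels = out, outlierFactor = as.numeric(outlierFactor),
      modeRatio = mode_ratio, histogram = h)
}
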