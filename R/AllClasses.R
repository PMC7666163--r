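#' @import methods
NULL

## ---------------------------------------------------------------------------
## Detection-side classes
## ---------------------------------------------------------------------------

#' Tunable parameters of the event-detection pipeline
#'
#' Holds every tunable of the threshold-based segmentation pipeline: the
#' open-current window `(oLow, oUp)` used for baseline and noise estimation,
#' the threshold multiplier `kSigma` (the detection threshold is
#' `b_o - kSigma * sigma_o`), the segment size used for local baseline and
#' noise estimation, the dwell-time window `[tMin, tMax]` in data time points,
#' and the fractional residual-current window `[bMin, bMax]` applied to
#' `min(I_r)/b_o`.
#'
#' @slot oLow,oUp numeric(1). Lower/upper bound (pA) of the open-pore current.
#'   `NA` means: estimate per trace from the mode of a 1-pA histogram.
#' @slot kSigma numeric(1). Threshold multiplier; default 10.
#' @slot segmentSize integer(1). Samples per segment for local baseline/noise
#'   estimation; default 100000.
#' @slot tMin,tMax integer(1). Dwell-time window in data time points
#'   (defaults 4 and 300, i.e. 1.3--100 ms at 3.012 kHz).
#' @slot bMin,bMax numeric(1). Window on `min(I_r)/b_o` (defaults 0 and 0.55).
#' @slot inclusiveBounds logical(1). If `TRUE` (default) the dwell-time and
#'   ratio windows are closed (`<=`); if `FALSE`, open (`<`).
#' @slot noiseMode character(1). `"median"` (median of per-segment standard
#'   deviations, robust to event-dense segments) or `"global"` (one standard
#'   deviation over all in-bounds samples).
#' @slot baselineMode character(1). `"segment"` (baseline and threshold
#'   recomputed per segment; default) or `"global"` (one baseline per channel).
#' @slot qcSdFactor numeric(1). A channel whose per-segment noise varies by
#'   more than this factor (max/min) is flagged as having an unstable baseline.
#' @seealso [detectionParams()], [detectEvents()]
#' @exportClass DetectionParams
setClass("DetectionParams",
  slots = c(
    oLow = "numeric", oUp = "numeric", kSigma = "numeric",
    segmentSize = "integer", tMin = "integer", tMax = "integer",
    bMin = "numeric", bMax = "numeric", inclusiveBounds = "logical",
    noiseMode = "character", baselineMode = "character",
    qcSdFactor = "numeric"
  ),
  prototype = list(
    oLow = NA_real_, oUp = NA_real_, kSigma = 10,
    segmentSize = 100000L, tMin = 4L, tMax = 300L,
    bMin = 0, bMax = 0.55, inclusiveBounds = TRUE,
    noiseMode = "median", baselineMode = "segment",
    qcSdFactor = 3
  )
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (!is.na(object@oLow) && !is.na(object@oUp) && object@oLow >= object@oUp)
    msg <- c(msg, "oLow must be < oUp")
  if (object@kSigma < 0) msg <- c(msg, "kSigma must be >= 0")
  if (object@segmentSize < 1L) msg <- c(msg, "segmentSize must be >= 1")
  if (!(object@tMin > 0L && object@tMin < object@tMax))
    msg <- c(msg, "need 0 < tMin < tMax")
  if (!(object@bMin >= 0 && object@bMin < object@bMax && object@bMax <= 1))
    msg <- c(msg, "need 0 <= bMin < bMax <= 1")
  if (!object@noiseMode %in% c("median", "global"))
    msg <- c(msg, "noiseMode must be 'median' or 'global'")
  if (!object@baselineMode %in% c("segment", "global"))
    msg <- c(msg, "baselineMode must be 'segment' or 'global'")
  if (object@qcSdFactor <= 1) msg <- c(msg, "qcSdFactor must be > 1")
  if (length(msg)) msg else TRUE
})

#' One channel's raw current trace
#'
#' An ordered sequence of current samples (pA) from a single nanopore channel,
#' with its sampling metadata. The applied potential is negative by the
#' convention of the recording device.
#'
#' @slot channelId integer(1). Channel number.
#' @slot samples numeric. Current samples in acquisition order, pA.
#' @slot samplingRateHz numeric(1). Sampling rate; these devices acquire at
#'   3012 Hz (3 data points per ms).
#' @slot voltageMv numeric(1). Applied potential, mV (negative).
#' @slot source character(1). Free-text provenance label.
#' @seealso [nanoporeTrace()], [readCsvTrace()], [readBulkFast5()]
#' @exportClass NanoporeTrace
setClass("NanoporeTrace",
  slots = c(
    channelId = "integer", samples = "numeric",
    samplingRateHz = "numeric", voltageMv = "numeric", source = "character"
  ),
  prototype = list(
    channelId = 1L, samples = numeric(), samplingRateHz = 3012,
    voltageMv = -210, source = "memory"
  )
)

setValidity("NanoporeTrace", function(object) {
  msg <- character()
  if (length(object@samplingRateHz) != 1L || object@samplingRateHz <= 0)
    msg <- c(msg, "samplingRateHz must be a single positive number")
  if (anyNA(object@samples)) msg <- c(msg, "samples must not contain NA")
  if (length(object@channelId) != 1L) msg <- c(msg, "channelId must be scalar")
  if (length(msg)) msg else TRUE
})

#' Per-channel baseline, noise and threshold summary
#'
#' @slot channelId integer(1).
#' @slot bO numeric(1). Open-pore baseline, the median of in-bounds samples, pA.
#' @slot sigmaO numeric(1). Open-pore noise, pA.
#' @slot bAll numeric(1). Detection threshold `bO - kSigma * sigmaO`, pA.
#' @slot nInbounds integer(1). Number of samples strictly inside `(oLow, oUp)`.
#' @slot qcPass logical(1). `FALSE` when baseline/noise estimation failed
#'   (blocked or dead pore, or wrong bounds).
#' @slot qcStable logical(1). `FALSE` when per-segment noise varies by more
#'   than the configured factor (unstable baseline).
#' @slot segments data.frame. Per-segment baseline/noise/threshold (columns
#'   `start`, `end`, `b_o`, `sigma_o`, `b_all`; 0-based half-open spans).
#' @exportClass ChannelBaseline
setClass("ChannelBaseline",
  slots = c(
    channelId = "integer", bO = "numeric", sigmaO = "numeric",
    bAll = "numeric", nInbounds = "integer",
    qcPass = "logical", qcStable = "logical", segments = "data.frame"
  ),
  prototype = list(
    channelId = 1L, bO = NA_real_, sigmaO = NA_real_, bAll = NA_real_,
    nInbounds = 0L, qcPass = FALSE, qcStable = TRUE,
    segments = data.frame()
  )
)

setValidity("ChannelBaseline", function(object) {
  msg <- character()
  if (isTRUE(object@qcPass)) {
    if (!is.finite(object@sigmaO) || object@sigmaO < 0)
      msg <- c(msg, "sigmaO must be >= 0")
    if (is.finite(object@bAll) && is.finite(object@bO) &&
        object@bAll > object@bO + 1e-9)
      msg <- c(msg, "bAll must be <= bO")
  }
  if (length(msg)) msg else TRUE
})

#' Table of accepted translocation events
#'
#' The result of running the detection pipeline over one or more channels.
#' `events` has one row per accepted event with columns `channel`, `i_o`
#' (the baseline against which the event was scored, pA), `i_r` (in-event
#' minimum current, pA), `i_mean` (in-event mean current, pA; informational,
#' not used by any filter), `ratio` (`i_r / i_o`), `start`, `end` (0-based
#' half-open sample indices) and `tau` (`end - start`, data time points).
#' `baselines` has one row per channel with columns `channel`, `b_o`,
#' `sigma_o`, `b_all`, `n_inbounds`, `qc_pass`, `qc_stable`.
#'
#' @slot events data.frame.
#' @slot baselines data.frame.
#' @slot params the [DetectionParams-class] used.
#' @exportClass EventTable
setClass("EventTable",
  slots = c(events = "data.frame", baselines = "data.frame",
            params = "DetectionParams"),
  prototype = list(
    events = data.frame(
      channel = integer(), i_o = numeric(), i_r = numeric(),
      i_mean = numeric(), ratio = numeric(),
      start = integer(), end = integer(), tau = integer()
    ),
    baselines = data.frame(
      channel = integer(), b_o = numeric(), sigma_o = numeric(),
      b_all = numeric(), n_inbounds = integer(),
      qc_pass = logical(), qc_stable = logical()
    )
  )
)

.EVENT_COLS <- c("channel", "i_o", "i_r", "i_mean", "ratio",
                 "start", "end", "tau")

setValidity("EventTable", function(object) {
  msg <- character()
  if (!all(.EVENT_COLS %in% names(object@events)))
    msg <- c(msg, paste("events must have columns:",
                        paste(.EVENT_COLS, collapse = ", ")))
  ev <- object@events
  if (nrow(ev)) {
    if (any(ev$start >= ev$end)) msg <- c(msg, "need start < end")
    if (any(abs(ev$tau - (ev$end - ev$start)) > 0))
      msg <- c(msg, "tau must equal end - start")
    if (any(abs(ev$ratio - ev$i_r / ev$i_o) > 1e-6))
      msg <- c(msg, "ratio must equal i_r / i_o")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Reporting / decision classes
## ---------------------------------------------------------------------------

#' Histogram of fractional residual current
#'
#' Counts of accepted events binned by `I_r/I_o`. Bins are left-closed,
#' right-open, except the last bin which is closed on both sides, so the
#' bins tile `[0, bMax]` exactly.
#'
#' @slot binWidth numeric(1). Default 0.05.
#' @slot breaks numeric. Bin edges.
#' @slot mids numeric. Bin midpoints.
#' @slot counts integer. Events per bin.
#' @slot total integer. Sum of counts.
#' @exportClass RatioHistogram
setClass("RatioHistogram",
  slots = c(binWidth = "numeric", breaks = "numeric", mids = "numeric",
            counts = "integer", total = "integer")
)

setValidity("RatioHistogram", function(object) {
  msg <- character()
  if (length(object@breaks) != length(object@counts) + 1L)
    msg <- c(msg, "breaks must have length(counts) + 1")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (sum(object@counts) != object@total)
    msg <- c(msg, "total must equal sum(counts)")
  if (length(msg)) msg else TRUE
})

#' Per-experiment count summary with outlier channels
#'
#' @slot perChannelCounts named integer. Accepted events per channel.
#' @slot totalCounts integer(1). Total accepted events (outliers included).
#' @slot outlierChannels integer. Channels whose count exceeds
#'   `outlierFactor` times the median nonzero per-channel count.
#' @slot outlierFactor numeric(1).
#' @slot modeRatio numeric(1). Midpoint of the histogram bin with maximal
#'   count, `(I_r/I_o)_max`; ties resolve to the lowest bin.
#' @slot histogram the underlying [RatioHistogram-class].
#' @exportClass ExperimentSummary
setClass("ExperimentSummary",
  slots = c(
    perChannelCounts = "integer", totalCounts = "integer",
    outlierChannels = "integer", outlierFactor = "numeric",
    modeRatio = "numeric", histogram = "RatioHistogram"
  )
)

setValidity("ExperimentSummary", function(object) {
  msg <- character()
  if (sum(object@perChannelCounts) != object@totalCounts)
    msg <- c(msg, "totalCounts must equal sum(perChannelCounts)")
  chan <- as.integer(names(object@perChannelCounts))
  if (!all(object@outlierChannels %in% chan))
    msg <- c(msg, "outlierChannels must be a subset of channels present")
  if (length(msg)) msg else TRUE
})

#' Probe-silencing presence/absence call
#'
#' The decision rule compares the event count of a probe-only experiment to
#' that of the probe + unknown-sample mixture. The target is called present
#' when the probe count is at least `threshold` (default 3) times the mixture
#' count, after optional subtraction of a buffer-control count (floored at
#' zero) from both.
#'
#' @slot probeCounts,mixtureCounts numeric(1). Raw event counts.
#' @slot bufferCounts numeric(1). Buffer-control count, or `NA` when not used.
#' @slot adjustedProbe,adjustedMixture numeric(1). Counts after buffer
#'   subtraction (equal to the raw counts when no buffer is supplied).
#' @slot ratio numeric(1). `adjustedProbe / adjustedMixture` (Inf when the
#'   adjusted mixture count is 0 and the probe count is positive).
#' @slot call character(1). `"present"`, `"absent"` or `"indeterminate"`.
#' @slot threshold numeric(1). Decision threshold, default 3.
#' @exportClass SilencingDecision
setClass("SilencingDecision",
  slots = c(
    probeCounts = "numeric", mixtureCounts = "numeric",
    bufferCounts = "numeric", adjustedProbe = "numeric",
    adjustedMixture = "numeric", ratio = "numeric",
    call = "character", threshold = "numeric"
  )
)

setValidity("SilencingDecision", function(object) {
  if (!object@call %in% c("present", "absent", "indeterminate"))
    return("call must be 'present', 'absent' or 'indeterminate'")
  TRUE
})

## ---------------------------------------------------------------------------
## Probe-design classes
## ---------------------------------------------------------------------------

.BASES <- c("A", "C", "G", "T", "U")
.SUGARS <- c("deoxy", "ribo", "2OMe")

#' Annotated nucleic-acid sequence
#'
#' A sequence of residues, each a (base, sugar) pair, so that DNA, RNA and
#' 2'-O-methyl chemistry can coexist in one oligo as in chimeric probe
#' designs ("mU" denotes 2'-O-methyl-U). A T nucleobase on a ribose or
#' 2'-O-methyl sugar is the 5-methyl-U equivalent.
#'
#' @slot bases character. One of `A`, `C`, `G`, `T`, `U` per residue.
#' @slot sugars character. One of `"deoxy"`, `"ribo"`, `"2OMe"` per residue.
#' @slot name character(1).
#' @seealso [nucleicSequence()], [reverseComplement()]
#' @exportClass NucleicSequence
setClass("NucleicSequence",
  slots = c(bases = "character", sugars = "character", name = "character"),
  prototype = list(bases = character(), sugars = character(), name = "")
)

setValidity("NucleicSequence", function(object) {
  msg <- character()
  if (length(object@bases) != length(object@sugars))
    msg <- c(msg, "bases and sugars must have equal length")
  if (!all(object@bases %in% .BASES))
    msg <- c(msg, "bases must be A, C, G, T or U")
  if (!all(object@sugars %in% .SUGARS))
    msg <- c(msg, "sugars must be 'deoxy', 'ribo' or '2OMe'")
  if (length(msg)) msg else TRUE
})

#' An osmylation protocol (reagent concentration and incubation time)
#'
#' Constants for the lettered manufacturing protocols: `o` = 40 min with
#' 2.6 mM reagent (stock made without pre-dissolving bipyridine), `a` = 45 min
#' with 2.6 mM, `b` = 30 min with 2.6 mM (recommended for T-osmylation),
#' `c` = 30 min with 3.9 mM (recommended for partial U/C osmylation of T-free
#' oligos), `d` = 30 min with 5.25 mM (T-free probes needing more tags).
#'
#' @slot id character(1). One of `o`, `a`, `b`, `c`, `d`.
#' @slot osbpMm numeric(1). Reagent concentration, mM.
#' @slot timeMin numeric(1). Incubation time, min.
#' @seealso [osmylationProtocol()]
#' @exportClass OsmylationProtocol
setClass("OsmylationProtocol",
  slots = c(id = "character", osbpMm = "numeric", timeMin = "numeric")
)

setValidity("OsmylationProtocol", function(object) {
  msg <- character()
  if (object@osbpMm <= 0) msg <- c(msg, "osbpMm must be > 0")
  if (object@timeMin < 0) msg <- c(msg, "timeMin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Relative osmylation reactivities with an absolute calibration
#'
#' Relative rates per nucleobase, with separate deoxyribose and ribose scales
#' each normalised to C = 1: on the deoxy scale T = 28 and dU = 3.75; on the
#' ribo scale 5-MeU (the T nucleobase) = 44 and U = 4.7. Purines are
#' unreactive. `rateRef` converts relative rates to absolute
#' pseudo-first-order rate constants (per mM per min); the default is
#' anchored so that U under protocol c is labeled with probability 0.43,
#' matching the observed slope of tags-per-molecule against U count.
#'
#' @slot ratesDeoxy,ratesRibo named numeric with elements `T`, `U`, `C`.
#' @slot rateRef numeric(1). Absolute calibration constant, mM^-1 min^-1.
#' @seealso [reactivityScale()], [predictOsmylation()]
#' @exportClass ReactivityScale
setClass("ReactivityScale",
  slots = c(ratesDeoxy = "numeric", ratesRibo = "numeric", rateRef = "numeric")
)

setValidity("ReactivityScale", function(object) {
  msg <- character()
  need <- c("T", "U", "C")
  if (!all(need %in% names(object@ratesDeoxy)) ||
      !all(need %in% names(object@ratesRibo)))
    msg <- c(msg, "rates must be named with T, U and C")
  if (any(object@ratesDeoxy <= 0) || any(object@ratesRibo <= 0))
    msg <- c(msg, "relative rates must be > 0")
  if (object@rateRef <= 0) msg <- c(msg, "rateRef must be > 0")
  if (length(msg)) msg else TRUE
})

#' A designed osmylated probe for one target
#'
#' @slot target the target [NucleicSequence-class].
#' @slot probe the designed probe sequence.
#' @slot complementaryRegion integer(2). 1-based inclusive span of the probe
#'   that reverse-complements the target.
#' @slot fivePrimeTail integer(1). Number of dT residues prepended at 5'.
#' @slot threePrimeTail integer(1). Number of dA residues appended at 3'.
#' @slot taggedPositions integer. Predicted tag positions (1-based, in probe
#'   coordinates).
#' @slot expectedOsBp numeric(1). Expected tags per molecule under the
#'   design's protocol.
#' @slot protocol character(1). Protocol id used for the prediction.
#' @seealso [designProbe()], [hybridizationFeasibility()], [recommendVoltage()]
#' @exportClass ProbeDesign
setClass("ProbeDesign",
  slots = c(
    target = "NucleicSequence", probe = "NucleicSequence",
    complementaryRegion = "integer", fivePrimeTail = "integer",
    threePrimeTail = "integer", taggedPositions = "integer",
    expectedOsBp = "numeric", protocol = "character"
  )
)

setValidity("ProbeDesign", function(object) {
  msg <- character()
  n <- length(object@probe@bases)
  cr <- object@complementaryRegion
  if (length(cr) != 2L || cr[1] < 1L || cr[2] > n || cr[1] > cr[2])
    msg <- c(msg, "complementaryRegion must be a valid span within the probe")
  if (any(object@taggedPositions < 1L) || any(object@taggedPositions > n))
    msg <- c(msg, "taggedPositions must lie within the probe")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

.SPECIES_COLS <- c("name", "event_rate_hz", "ratio_center", "ratio_spread",
                   "tau_log_mean", "tau_log_sd", "voltage_threshold_mv")

#' Configuration of a synthetic multi-channel experiment
#'
#' Generative parameters for synthetic current traces: a constant open-pore
#' current with Gaussian noise, rectangular blockade events with
#' species-specific depth and log-normal duration, Poisson arrivals per
#' channel, a seeded fraction of high-rate outlier channels, and optional
#' per-species voltage gating (a species emits events only when the applied
#' potential magnitude reaches its threshold).
#'
#' @slot nChannels integer(1).
#' @slot durationS numeric(1). Trace duration, s.
#' @slot samplingRateHz numeric(1). Default 3012 (3 points per ms).
#' @slot iOPa numeric(1). Open-pore current, pA.
#' @slot noiseSdPa numeric(1). Open-pore noise, pA.
#' @slot voltageMv numeric(1). Applied potential, mV (negative).
#' @slot species data.frame. One row per species; see [speciesProfile()].
#' @slot outlierFraction numeric(1). Fraction of channels planted as
#'   outliers; default 0.025.
#' @slot outlierRateFactor numeric(1). Rate multiplier for outlier channels;
#'   default 10.
#' @slot seed integer(1). Master seed; simulation is deterministic given the
#'   seed and channel id.
#' @seealso [simConfig()], [simulateExperiment()]
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(
    nChannels = "integer", durationS = "numeric", samplingRateHz = "numeric",
    iOPa = "numeric", noiseSdPa = "numeric", voltageMv = "numeric",
    species = "data.frame", outlierFraction = "numeric",
    outlierRateFactor = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (object@samplingRateHz <= 0) msg <- c(msg, "samplingRateHz must be > 0")
  if (object@noiseSdPa < 0) msg <- c(msg, "noiseSdPa must be >= 0")
  if (!all(.SPECIES_COLS %in% names(object@species)))
    msg <- c(msg, paste("species must have columns:",
                        paste(.SPECIES_COLS, collapse = ", ")))
  else {
    sp <- object@species
    if (any(sp$event_rate_hz < 0)) msg <- c(msg, "event rates must be >= 0")
    if (any(sp$ratio_center <= 0 | sp$ratio_center >= 1))
      msg <- c(msg, "ratio_center must be in (0, 1)")
  }
  if (object@outlierFraction < 0 || object@outlierFraction > 1)
    msg <- c(msg, "outlierFraction must be in [0, 1]")
  if (object@outlierRateFactor <= 0)
    msg <- c(msg, "outlierRateFactor must be > 0")
  if (length(msg)) msg else TRUE
})
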