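#' @include AllGenerics.R
NULL

#' Accessors for traces, event tables, histograms and decisions
#'
#' Standard accessor functions; use these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @return The slot value; see the class documentation for semantics.
#' @name accessors
#' @aliases channelId samples samplingRateHz voltageMv events baselines
#'   nEvents binCounts binMids totalCounts perChannelCounts outlierChannels
#'   modeRatio silencingCall countRatio seqBases seqSugars probeSeq targetSeq
#'   taggedPositions expectedOsBp complementaryRegion
NULL

#' @rdname accessors
#' @exportMethod channelId
setMethod("channelId", "NanoporeTrace", function(x) x@channelId)

#' @rdname accessors
#' @exportMethod samples
setMethod("samples", "NanoporeTrace", function(x) x@samples)

#' @rdname accessors
#' @exportMethod samplingRateHz
setMethod("samplingRateHz", "NanoporeTrace", function(x) x@samplingRateHz)

#' @rdname accessors
#' @exportMethod voltageMv
setMethod("voltageMv", "NanoporeTrace", function(x) x@voltageMv)

#' @rdname accessors
setMethod("length", "NanoporeTrace", function(x) length(x@samples))

#' @rdname accessors
#' @exportMethod events
setMethod("events", "EventTable", function(x) x@events)

#' @rdname accessors
#' @exportMethod baselines
setMethod("baselines", "EventTable", function(x) x@baselines)

#' @rdname accessors
#' @exportMethod nEvents
setMethod("nEvents", "EventTable", function(x) nrow(x@events))

#' @rdname accessors
#' @exportMethod binCounts
setMethod("binCounts", "RatioHistogram", function(x) x@counts)

#' @rdname accessors
#' @exportMethod binMids
setMethod("binMids", "RatioHistogram", function(x) x@mids)

#' @rdname accessors
#' @exportMethod totalCounts
setMethod("totalCounts", "RatioHistogram", function(x) x@total)

#' @rdname accessors
setMethod("totalCounts", "ExperimentSummary", function(x) x@totalCounts)

#' @rdname accessors
#' @exportMethod perChannelCounts
setMethod("perChannelCounts", "ExperimentSummary",
          function(x) x@perChannelCounts)

#' @rdname accessors
#' @exportMethod outlierChannels
setMethod("outlierChannels", "ExperimentSummary", function(x) x@outlierChannels)

#' @rdname accessors
#' @exportMethod modeRatio
setMethod("modeRatio", "ExperimentSummary", function(x) x@modeRatio)

#' @rdname accessors
#' @exportMethod silencingCall
setMethod("silencingCall", "SilencingDecision", function(x) x@call)

#' @rdname accessors
#' @exportMethod countRatio
setMethod("countRatio", "SilencingDecision", function(x) x@ratio)

#' @rdname accessors
#' @exportMethod seqBases
setMethod("seqBases", "NucleicSequence", function(x) x@bases)

#' @rdname accessors
#' @exportMethod seqSugars
setMethod("seqSugars", "NucleicSequence", function(x) x@sugars)

#' @rdname accessors
setMethod("length", "NucleicSequence", function(x) length(x@bases))

#' @rdname accessors
#' @exportMethod probeSeq
setMethod("probeSeq", "ProbeDesign", function(x) x@probe)

#' @rdname accessors
#' @exportMethod targetSeq
setMethod("targetSeq", "ProbeDesign", function(x) x@target)

#' @rdname accessors
#' @exportMethod taggedPositions
setMethod("taggedPositions", "ProbeDesign", function(x) x@taggedPositions)

#' @rdname accessors
#' @exportMethod expectedOsBp
setMethod("expectedOsBp", "ProbeDesign", function(x) x@expectedOsBp)

#' @rdname accessors
#' @exportMethod complementaryRegion
setMethod("complementaryRegion", "ProbeDesign",
          function(x) x@complementaryRegion)

## show methods -------------------------------------------------------------

setMethod("show", "NanoporeTrace", function(object) {
  cat(sprintf(
    "NanoporeTrace: channel %d, %d samples @ %.0f Hz (%.1f s), %+.0f mV [%s]\n",
    object@channelId, length(object@samples), object@samplingRateHz,
    length(object@samples) / object@samplingRateHz,
    object@voltageMv, object@source))
})

setMethod("show", "DetectionParams", function(object) {
  bounds <- if (is.na(object@oLow)) "auto" else
    sprintf("(%.1f, %.1f) pA", object@oLow, object@oUp)
  cat("DetectionParams:\n",
      sprintf("  open-current bounds: %s\n", bounds),
      sprintf("  threshold: b_o - %.1f * sigma_o; segment size %d (%s baseline, %s noise)\n",
              object@kSigma, object@segmentSize, object@baselineMode,
              object@noiseMode),
      sprintf("  filters: %d <= tau <= %d points, %.2f <= min(I_r)/b_o <= %.2f (%s)\n",
              object@tMin, object@tMax, object@bMin, object@bMax,
              if (object@inclusiveBounds) "inclusive" else "strict"),
      sep = "")
})

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events across %d channel(s)\n",
              nrow(object@events), nrow(object@baselines)))
  if (nrow(object@baselines)) {
    ok <- sum(object@baselines$qc_pass)
    cat(sprintf("  channels passing baseline QC: %d/%d\n",
                ok, nrow(object@baselines)))
  }
  if (nrow(object@events)) {
    cat("  first events:\n")
    print(utils::head(object@events, 5L))
  }
})

setMethod("show", "RatioHistogram", function(object) {
  cat(sprintf("RatioHistogram: %d events in %d bins of width %.2f\n",
              object@total, length(object@counts), object@binWidth))
})

setMethod("show", "ExperimentSummary", function(object) {
  cat(sprintf(
    "ExperimentSummary: %d events on %d channel(s); (I_r/I_o)_max = %.3f\n",
    object@totalCounts, length(object@perChannelCounts), object@modeRatio))
  if (length(object@outlierChannels))
    cat("  outlier channels (> ", object@outlierFactor,
        "x median): ", paste(object@outlierChannels, collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "SilencingDecision", function(object) {
  cat(sprintf(
    "SilencingDecision: %s (probe/mixture ratio %.3g, threshold %.3g)\n",
    object@call, object@ratio, object@threshold))
  if (!is.na(object@bufferCounts))
    cat(sprintf("  buffer-adjusted counts: probe %g, mixture %g (buffer %g)\n",
                object@adjustedProbe, object@adjustedMixture,
                object@bufferCounts))
})

setMethod("show", "NucleicSequence", function(object) {
  nm <- if (nzchar(object@name)) paste0(" '", object@name, "'") else ""
  cat(sprintf("NucleicSequence%s (%d nt): %s\n", nm, length(object@bases),
              as.character(object)))
})

setMethod("show", "ProbeDesign", function(object) {
  cat("ProbeDesign:\n")
  cat("  target: ", as.character(object@target), "\n", sep = "")
  cat("  probe:  ", as.character(object@probe), "\n", sep = "")
  cat(sprintf("  complementary region: positions %d-%d; tails 5':%d dT / 3':%d dA\n",
              object@complementaryRegion[1], object@complementaryRegion[2],
              object@fivePrimeTail, object@threePrimeTail))
  cat(sprintf("  predicted tags at: %s (expected %.2f per molecule, protocol %s)\n",
              if (length(object@taggedPositions))
                paste(object@taggedPositions, collapse = ", ") else "none",
              object@expectedOsBp, object@protocol))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d channel(s) x %.1f s @ %.0f Hz; I_o %.0f pA (sd %.1f), %+.0f mV\n",
    object@nChannels, object@durationS, object@samplingRateHz,
    object@iOPa, object@noiseSdPa, object@voltageMv))
  cat(sprintf("  species: %s; outliers %.1f%% at %gx rate; seed %d\n",
              paste(object@species$name, collapse = ", "),
              100 * object@outlierFraction, object@outlierRateFactor,
              object@seed))
})
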