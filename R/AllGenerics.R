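#' @include AllClasses.R
NULL

#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))

#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @export
setGeneric("samplingRateHz", function(x) standardGeneric("samplingRateHz"))

#' @export
setGeneric("voltageMv", function(x) standardGeneric("voltageMv"))

#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @export
setGeneric("baselines", function(x) standardGeneric("baselines"))

#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @export
setGeneric("binMids", function(x) standardGeneric("binMids"))

#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @export
setGeneric("perChannelCounts", function(x) standardGeneric("perChannelCounts"))

#' @export
setGeneric("outlierChannels", function(x) standardGeneric("outlierChannels"))

#' @export
setGeneric("modeRatio", function(x) standardGeneric("modeRatio"))

#' @export
setGeneric("silencingCall", function(x) standardGeneric("silencingCall"))

#' @export
setGeneric("countRatio", function(x) standardGeneric("countRatio"))

#' @export
setGeneric("seqBases", function(x) standardGeneric("seqBases"))

#' @export
setGeneric("seqSugars", function(x) standardGeneric("seqSugars"))

#' @export
setGeneric("probeSeq", function(x) standardGeneric("probeSeq"))

#' @export
setGeneric("targetSeq", function(x) standardGeneric("targetSeq"))

#' @export
setGeneric("taggedPositions", function(x) standardGeneric("taggedPositions"))

#' @export
setGeneric("expectedOsBp", function(x) standardGeneric("expectedOsBp"))

#' @export
setGeneric("complementaryRegion",
           function(x) standardGeneric("complementaryRegion"))

#' @export
setGeneric("reverseComplement", function(x, ...)
  standardGeneric("reverseComplement"))
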