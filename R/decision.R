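#' @include reporting.R
NULL

#' Presence/absence call from probe vs mixture event counts
#'
#' The probe-silencing readout: the target is called present when the event
#' count of the probe-only experiment is at least `threshold` times (default
#' 3, the proposed lower detectability limit) the count of the probe +
#' sample mixture. When a buffer-control count is supplied it is subtracted
#' from both counts first (floored at zero). If the adjusted mixture count
#' is zero while the probe count is positive the call is `present`; if the
#' adjusted probe count is zero the probe itself was undetectable and the
#' call is `indeterminate`.
#'
#' @param probeCounts event count of the probe-alone experiment (>= 0).
#' @param mixtureCounts event count of the probe + sample experiment (>= 0).
#' @param bufferCounts optional buffer-control count to subtract.
#' @param threshold decision threshold, default 3 (inclusive).
#' @return A [SilencingDecision-class].
#' @examples
#' decidePresence(194810, 19647, bufferCounts = 7680)  # present, ratio ~15.6
#' decidePresence(3000, 1000)                          # boundary: present
#' @export
decidePresence <- function(probeCounts, mixtureCounts, bufferCounts = NA,
                           threshold = 3) {
  if (probeCounts < 0 || mixtureCounts < 0 ||
      (!is.na(bufferCounts) && bufferCounts < 0))
    stop("validation error: counts must be >= 0")
  stopifnot(threshold > 0)
  adj <- function(x) if (is.na(bufferCounts)) x else max(x - bufferCounts, 0)
  p <- adj(probeCounts)
  m <- adj(mixtureCounts)
  if (p == 0) {
    call <- "indeterminate"
    ratio <- NaN
  } else if (m == 0) {
    call <- "present"
    ratio <- Inf
  } else {
    ratio <- p / m
    call <- if (ratio >= threshold) "present" else "absent"
  }
  new("SilencingDecision",
      probeCounts = as.numeric(probeCounts),
      mixtureCounts = as.numeric(mixtureCounts),
      bufferCounts = as.numeric(bufferCounts),
      adjustedProbe = as.numeric(p), adjustedMixture = as.numeric(m),
      ratio = ratio, call = call, threshold = as.numeric(threshold))
}

#' One-sided quantification of the target from a silencing call
#'
#' The assay counts probe translocations, not hybrid molecules, and
#' proportionality between counts and concentration is not assumed, so
#' quantification is a one-sided bound on the target load plus a recommended
#' next probe load. A `present` call (silencing observed) implies at least
#' as much target as probe (1:1 hybrid); the next experiment should raise
#' the probe load by a factor of 5. An `absent` call bounds the target below
#' the probe load; lower the next load by a factor of 5. Accuracy of the
#' resulting bracket is about 30%.
#'
#' @param decision a [SilencingDecision-class].
#' @param probeLoadAmol known probe load, amol (> 0).
#' @return A list with elements `bound` (`">="` or `"<"`), `boundAmol`,
#'   `nextLoadAmol`, and `accuracyNote`.
#' @examples
#' d <- decidePresence(3000, 500)
#' quantifyTarget(d, probeLoadAmol = 3.5)
#' @export
quantifyTarget <- function(decision, probeLoadAmol) {
  stopifnot(is(decision, "SilencingDecision"), probeLoadAmol > 0)
  if (decision@call == "indeterminate")
    stop("quantification refused: probe undetectable, test void")
  if (decision@call == "present")
    list(bound = ">=", boundAmol = probeLoadAmol,
         nextLoadAmol = probeLoadAmol * 5,
         accuracyNote = "about 30% accuracy")
  else
    list(bound = "<", boundAmol = probeLoadAmol,
         nextLoadAmol = probeLoadAmol / 5,
         accuracyNote = "about 30% accuracy")
}

#' Molecule count in a sample
#'
#' @param volumeUl sample volume, microlitres (> 0).
#' @param concentrationMolar molar concentration (> 0).
#' @return List with `moles`, `amol` (attomoles), `pmol` (picomoles) and
#'   `molecules` (Avogadro-scaled count).
#' @examples
#' moleculesInSample(10, 10e-15)  # 0.1 amol, ~60,000 molecules
#' @export
moleculesInSample <- function(volumeUl, concentrationMolar) {
  if (volumeUl <= 0 || concentrationMolar <= 0)
    stop("validation error: volume and concentration must be > 0")
  avogadro <- 6.02214076e23
  moles <- volumeUl * 1e-6 * concentrationMolar
  list(moles = moles, amol = moles * 1e18, pmol = moles * 1e12,
       molecules = moles * avogadro)
}

#' Convert data time points to milliseconds
#'
#' @param points dwell time in data time points.
#' @param samplingRateHz sampling rate, default 3012 Hz (3 points per ms).
#' @return Time in ms.
#' @examples
#' pointsToMs(4)    # ~1.3 ms
#' pointsToMs(300)  # ~100 ms
#' @export
pointsToMs <- function(points, samplingRateHz = 3012) {
  stopifnot(samplingRateHz > 0)
  1000 * points / samplingRateHz
}
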