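#' @include sequences.R
NULL

.PROTOCOLS <- list(
  o = c(osbp_mm = 2.6,  time_min = 40),
  a = c(osbp_mm = 2.6,  time_min = 45),
  b = c(osbp_mm = 2.6,  time_min = 30),
  c = c(osbp_mm = 3.9,  time_min = 30),
  d = c(osbp_mm = 5.25, time_min = 30)
)

#' Look up a lettered osmylation protocol
#'
#' @param id one of `"o"`, `"a"`, `"b"`, `"c"`, `"d"`; see
#'   [OsmylationProtocol-class] for the constants.
#' @return An [OsmylationProtocol-class].
#' @examples
#' osmylationProtocol("c")  # 30 min with 3.9 mM
#' @export
osmylationProtocol <- function(id = c("b", "c", "d", "o", "a")) {
  id <- match.arg(id)
  p <- .PROTOCOLS[[id]]
  new("OsmylationProtocol", id = id, osbpMm = unname(p["osbp_mm"]),
      timeMin = unname(p["time_min"]))
}

#' Default reactivity scale
#'
#' Relative osmylation rates per nucleobase (deoxy scale: T = 28, dU = 3.75,
#' dC = 1; ribo scale: 5-MeU = 44, U = 4.7, C = 1; purines unreactive), with
#' the absolute calibration constant anchored so that a U residue under
#' protocol c (30 min, 3.9 mM) is labeled with probability 0.43 -- the
#' observed slope of average tags per molecule against U count.
#'
#' @param rateRef absolute calibration constant, mM^-1 min^-1. The default
#'   solves `1 - exp(-rateRef * 4.7 * 3.9 * 30) = 0.43`.
#' @return A [ReactivityScale-class].
#' @export
reactivityScale <- function(rateRef = -log(1 - 0.43) / (4.7 * 3.9 * 30)) {
  new("ReactivityScale",
      ratesDeoxy = c(T = 28, U = 3.75, C = 1),
      ratesRibo = c(T = 44, U = 4.7, C = 1),
      rateRef = rateRef)
}

#' Relative osmylation rate of each residue
#'
#' Purines are unreactive (rate 0). The nucleobase selects the rate; the
#' sugar selects the scale (deoxy vs ribo/2'-OMe), so a T nucleobase on a
#' 2'-OMe sugar is scored as 5-methyl-U.
#'
#' @param seq a [NucleicSequence-class].
#' @param scale a [ReactivityScale-class].
#' @return Numeric vector of relative rates, one per residue.
#' @export
relativeReactivity <- function(seq, scale = reactivityScale()) {
  stopifnot(is(seq, "NucleicSequence"), is(scale, "ReactivityScale"))
  vapply(seq_along(seq@bases), function(i) {
    b <- seq@bases[i]
    if (b %in% c("A", "G")) return(0)
    if (seq@sugars[i] == "deoxy") unname(scale@ratesDeoxy[b])
    else unname(scale@ratesRibo[b])
  }, numeric(1))
}

#' Theoretical chromophore ratio R(312/272)
#'
#' The 312/272 nm absorbance ratio expected at complete osmylation:
#' `2 * (number of T) / (total nt)` for T-only labeling, or
#' `2 * (number of pyrimidines) / (total nt)` when every pyrimidine carries
#' one tag. Ranges over `[0, 2]`.
#'
#' @param seq a [NucleicSequence-class] (or string accepted by
#'   [nucleicSequence()]).
#' @param mode `"T_only"` (default) or `"all_pyrimidines"`.
#' @return The theoretical ratio.
#' @examples
#' theoreticalR("GGG TAA CGC CAG GGT TTT TCC AGT CAC GAC")  # 0.467 (BJ4)
#' @export
theoreticalR <- function(seq, mode = c("T_only", "all_pyrimidines")) {
  mode <- match.arg(mode)
  if (is.character(seq)) seq <- nucleicSequence(seq)
  n <- length(seq@bases)
  if (!n) stop("validation error: empty sequence")
  k <- if (mode == "T_only") sum(seq@bases == "T")
       else sum(seq@bases %in% c("C", "T", "U"))
  2 * k / n
}

#' Average tags per molecule from an observed R(312/272)
#'
#' Inverts the chromophore relation: average tag count equals
#' `observed R(312/272) * (total nt) / 2`. Warns when the result exceeds the
#' pyrimidine count (physically impossible), if that count is supplied.
#'
#' @param rObserved observed 312/272 absorbance ratio (>= 0).
#' @param lengthNt oligo length in nucleotides (> 0).
#' @param pyrimidineCount optional pyrimidine count for the sanity warning.
#' @return Average number of tags per molecule.
#' @examples
#' avgOsBpFromR(1.044, 20)  # 10.44, the fully osmylated d(CT)10
#' @export
avgOsBpFromR <- function(rObserved, lengthNt, pyrimidineCount = NULL) {
  stopifnot(rObserved >= 0, lengthNt > 0)
  n <- rObserved * lengthNt / 2
  if (!is.null(pyrimidineCount) && n > pyrimidineCount)
    warning(sprintf(
      "average tag count %.3g exceeds the pyrimidine count %d", n,
      pyrimidineCount))
  n
}

#' Per-position osmylation probabilities under a protocol
#'
#' Pseudo-first-order kinetics (the reagent is in 20-fold excess over the
#' reactive pyrimidines): the probability that position j carries a tag
#' after the reaction is `1 - exp(-rateRef * relRate_j * C_mM * t_min)`;
#' purines never react. The expected tags per molecule is the sum of the
#' per-position probabilities. With the default calibration, a U residue
#' under protocol c has probability exactly 0.43.
#'
#' @param seq a [NucleicSequence-class] (or string).
#' @param protocol an [OsmylationProtocol-class] or protocol letter.
#' @param scale a [ReactivityScale-class].
#' @return List with `probabilities` (one per residue), `expectedOsBp`
#'   (their sum), and `protocol`.
#' @examples
#' p <- predictOsmylation(nucleicSequence("UUU", sugar = "ribo"), "c")
#' p$probabilities  # 0.43 each
#' @export
predictOsmylation <- function(seq, protocol = "b",
                              scale = reactivityScale()) {
  if (is.character(seq)) seq <- nucleicSequence(seq)
  if (is.character(protocol)) protocol <- osmylationProtocol(protocol)
  stopifnot(is(protocol, "OsmylationProtocol"))
  rel <- relativeReactivity(seq, scale)
  p <- 1 - exp(-scale@rateRef * rel * protocol@osbpMm * protocol@timeMin)
  list(probabilities = p, expectedOsBp = sum(p), protocol = protocol@id)
}

#' Predicted tag positions for a probe
#'
#' Deterministic tag model: an oligo containing T nucleobases is assumed to
#' be labeled with protocol b, which tags practically 100% of Ts and leaves
#' the other pyrimidines essentially untagged, so the tagged positions are
#' exactly the T positions. A T-free oligo is labeled under the supplied
#' protocol (default d) and positions with predicted probability at or above
#' `cutoff` are tagged.
#'
#' @inheritParams predictOsmylation
#' @param cutoff probability cutoff for T-free oligos, default 0.5.
#' @return Integer vector of 1-based tag positions.
#' @export
predictTaggedPositions <- function(seq, protocol = "d", cutoff = 0.5,
                                   scale = reactivityScale()) {
  if (is.character(seq)) seq <- nucleicSequence(seq)
  tpos <- which(seq@bases == "T")
  if (length(tpos)) return(tpos)
  p <- predictOsmylation(seq, protocol, scale)$probabilities
  which(p >= cutoff)
}

#' Sample per-molecule tag patterns (topoisomers)
#'
#' Partially osmylated preparations are mixtures of molecules carrying tags
#' at different pyrimidines. This draws independent Bernoulli tags per
#' position from the kinetic model, one row per molecule.
#'
#' @inheritParams predictOsmylation
#' @param n number of molecules to draw.
#' @param seed integer seed for reproducibility.
#' @return Logical matrix `n x length(seq)`; `TRUE` marks a tag.
#' @export
sampleTopoisomers <- function(seq, protocol = "c", n = 100L, seed = 1L,
                              scale = reactivityScale()) {
  if (is.character(seq)) seq <- nucleicSequence(seq)
  p <- predictOsmylation(seq, protocol, scale)$probabilities
  old <- .Random.seed.exists()
  set.seed(as.integer(seed))
  m <- matrix(stats::runif(n * length(p)) < rep(p, each = n), nrow = n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  m
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
}

#' Design an osmylated probe for a target oligo
#'
#' `mode = "plain_complement"` returns the exact deoxy reverse complement of
#' the target. `mode = "extended_mU"` (the general design for a highly
#' detectable probe) prepends `tails[1]` dT residues at the 5' end, takes
#' the deoxy reverse complement with every internal T replaced by
#' 2'-O-methyl-U (preserving base pairing while keeping internal tagging
#' minimal), and appends `tails[2]` dA residues at the 3' end to facilitate
#' pore entry. Tag positions and the expected tags per molecule are
#' predicted with protocol b when the probe contains T (T-osmylation), and
#' protocol d otherwise.
#'
#' @param target a [NucleicSequence-class] or sequence string (RNA strings
#'   are parsed with ribose sugars automatically if they contain U).
#' @param mode `"extended_mU"` (default) or `"plain_complement"`.
#' @param tails integer(2): number of 5' dT and 3' dA residues for
#'   `extended_mU`; default `c(3, 3)`.
#' @return A [ProbeDesign-class].
#' @examples
#' d <- designProbe("UGG AGU GUG ACA AUG GUG UUU G",
#'                  mode = "plain_complement")
#' as.character(probeSeq(d))  # "CAAACACCATTGTCACACTCCA"
#' @export
designProbe <- function(target, mode = c("extended_mU", "plain_complement"),
                        tails = c(3L, 3L)) {
  mode <- match.arg(mode)
  if (is.character(target)) {
    sug <- if (grepl("U", gsub("m", "", gsub("[[:space:]]", "", target))))
      "ribo" else "deoxy"
    target <- nucleicSequence(target, sugar = sug)
  }
  if (!length(target@bases)) stop("validation error: empty target")
  comp <- reverseComplement(target, sugar = "deoxy")
  if (mode == "plain_complement") {
    probe <- comp
    region <- c(1L, length(comp@bases))
    five <- 0L; three <- 0L
  } else {
    stopifnot(length(tails) == 2L, all(tails >= 0))
    bases <- comp@bases
    sugars <- comp@sugars
    int_t <- bases == "T"
    bases[int_t] <- "U"
    sugars[int_t] <- "2OMe"
    probe <- new("NucleicSequence",
                 bases = c(rep("T", tails[1]), bases, rep("A", tails[2])),
                 sugars = c(rep("deoxy", tails[1]), sugars,
                            rep("deoxy", tails[2])),
                 name = if (nzchar(target@name))
                   paste0(target@name, "_EXT(mU)") else "")
    region <- c(tails[1] + 1L, tails[1] + length(bases))
    five <- as.integer(tails[1]); three <- as.integer(tails[2])
  }
  proto <- if (any(probe@bases == "T")) "b" else "d"
  tags <- predictTaggedPositions(probe, protocol = proto)
  exp_tags <- predictOsmylation(probe, proto)$expectedOsBp
  new("ProbeDesign", target = target, probe = probe,
      complementaryRegion = as.integer(region),
      fivePrimeTail = five, threePrimeTail = three,
      taggedPositions = as.integer(tags), expectedOsBp = exp_tags,
      protocol = proto)
}

#' Best ungapped antiparallel duplex between two oligos
#'
#' Scans every ungapped antiparallel offset of the two sequences and returns
#' the offset maximizing the number of Watson-Crick pairs (A-T, A-U, G-C; no
#' wobble), together with the pair count and the number of G-C pairs. Ties
#' resolve to the smallest offset. The score is symmetric in its arguments.
#'
#' @param a,b [NucleicSequence-class] objects or sequence strings.
#' @return List with `maxPairs`, `gcPairs` and `offset` (shift of the
#'   reversed second sequence along the first).
#' @examples
#' duplexScore(strrep("CT", 10), "AGAGAGAGCCAGAGAGAGCCAGAGAGCCUUCA")
#' @export
duplexScore <- function(a, b) {
  if (is.character(a)) a <- nucleicSequence(a)
  if (is.character(b)) b <- nucleicSequence(b)
  if (!length(a@bases) || !length(b@bases))
    stop("validation error: empty sequence")
  x <- a@bases
  y <- rev(b@bases)
  nx <- length(x); ny <- length(y)
  isPair <- function(p, q)
    (p == "A" & (q == "T" | q == "U")) | (q == "A" & (p == "T" | p == "U")) |
    (p == "G" & q == "C") | (p == "C" & q == "G")
  best <- list(maxPairs = -1L, gcPairs = 0L, offset = 0L)
  for (off in seq.int(-(ny - 1L), nx - 1L)) {
    iy <- seq_len(ny)
    ix <- iy + off
    ok <- ix >= 1L & ix <= nx
    if (!any(ok)) next
    m <- isPair(x[ix[ok]], y[iy[ok]])
    np <- sum(m)
    if (np > best$maxPairs) {
      gc <- sum(m & x[ix[ok]] %in% c("G", "C"))
      best <- list(maxPairs = as.integer(np), gcPairs = as.integer(gc),
                   offset = as.integer(off))
    }
  }
  best
}

#' Hybridization feasibility from the tag layout
#'
#' A probe hybridizes with its target when a long enough contiguous stretch
#' of its complementary region is free of bulky tags; many tags spread over
#' a short sequence distort the helix and block duplex formation, whereas
#' adjacent tags clustered at one end leave the rest of the sequence free to
#' pair. Feasibility requires the longest untagged run within the
#' complementary region to reach `runMin` (default 8; probes observed to
#' fail have runs of at most 5, probes observed to hybridize have runs of at
#' least 8).
#'
#' @param design a [ProbeDesign-class], or a [NucleicSequence-class]/string
#'   (in which case tags default to its T positions and the complementary
#'   region to the whole sequence).
#' @param taggedPositions optional explicit 1-based tag positions.
#' @param region optional integer(2) complementary-region span.
#' @param runMin feasibility threshold on the longest untagged run.
#' @return List with `feasible`, `longestRun` and `runMin`.
#' @examples
#' hybridizationFeasibility("TCAACATCAGTCTGATAAGCTA")$feasible  # FALSE
#' hybridizationFeasibility("CAGTCACGACGTTGTAAAACGACGGCCAGT")$feasible  # TRUE
#' @export
hybridizationFeasibility <- function(design, taggedPositions = NULL,
                                     region = NULL, runMin = 8L) {
  if (is(design, "ProbeDesign")) {
    n <- length(design@probe@bases)
    tags <- design@taggedPositions
    span <- design@complementaryRegion
  } else {
    seq <- if (is.character(design)) nucleicSequence(design) else design
    n <- length(seq@bases)
    tags <- if (is.null(taggedPositions)) which(seq@bases == "T") else
      as.integer(taggedPositions)
    span <- if (is.null(region)) c(1L, n) else as.integer(region)
  }
  if (!is.null(taggedPositions)) tags <- as.integer(taggedPositions)
  if (!is.null(region)) span <- as.integer(region)
  idx <- span[1]:span[2]
  untagged <- !(idx %in% tags)
  longest <- if (any(untagged)) {
    r <- rle(untagged)
    max(r$lengths[r$values])
  } else 0L
  list(feasible = longest >= runMin, longestRun = as.integer(longest),
       runMin = as.integer(runMin))
}

#' Recommended applied voltage for a probe
#'
#' Probes carrying three or more adjacent tags (heavy crowding, e.g. an
#' osmylated 5' dT tail) require about -210 mV for efficient translocation;
#' probes with scattered tags translocate at -180 mV; an untagged oligo is
#' not detectable at the device's acquisition rate.
#'
#' @inheritParams hybridizationFeasibility
#' @return List with `voltageMv` (`NA` when undetectable) and `detectable`.
#' @export
recommendVoltage <- function(design, taggedPositions = NULL) {
  if (is(design, "ProbeDesign")) {
    tags <- design@taggedPositions
  } else {
    seq <- if (is.character(design)) nucleicSequence(design) else design
    tags <- if (is.null(taggedPositions)) which(seq@bases == "T") else
      as.integer(taggedPositions)
  }
  if (!is.null(taggedPositions)) tags <- as.integer(taggedPositions)
  if (!length(tags))
    return(list(voltageMv = NA_integer_, detectable = FALSE))
  tags <- sort(tags)
  has3run <- FALSE
  if (length(tags) >= 3) {
    r <- rle(diff(tags) == 1L)
    has3run <- any(r$lengths[r$values] >= 2L)
  }
  list(voltageMv = if (has3run) -210L else -180L, detectable = TRUE)
}
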