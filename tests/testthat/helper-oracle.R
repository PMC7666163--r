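# Naive single-pass reference implementation of the detection pipeline:
# a plain sample-by-sample scan with explicit state, kept deliberately
# independent of the package's rle/step-threshold implementation.
naiveDetect <- function(y, oLow, oUp, kSigma = 10, tMin = 4L, tMax = 300L,
                        bMin = 0, bMax = 0.55) {
  inb <- y[y > oLow & y < oUp]
  b_o <- stats::median(inb)
  b_all <- b_o - kSigma * stats::sd(inb)
  starts <- integer(); ends <- integer()
  in_event <- FALSE; st <- 0L
  for (i in seq_along(y)) {
    if (y[i] < b_all) {
      if (!in_event) { in_event <- TRUE; st <- i }
    } else if (in_event) {
      starts <- c(starts, st); ends <- c(ends, i - 1L)
      in_event <- FALSE
    }
  }
  # an event still open at the trace end is truncated: drop it, and drop
  # events that began on the first sample
  keep <- starts > 1L
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(start = integer(), end = integer(), ratio = numeric())
  for (j in seq_along(starts)) {
    tau <- ends[j] - starts[j] + 1L
    r <- min(y[starts[j]:ends[j]]) / b_o
    if (tau >= tMin && tau <= tMax && r >= bMin && r <= bMax)
      out <- rbind(out, data.frame(start = starts[j] - 1L,
                                   end = ends[j], ratio = r))
  }
  # convert to the package's 0-based half-open convention
  if (nrow(out)) out$end <- out$end + 0L
  out
}

# inject rectangular dips into a Gaussian baseline; returns trace + truth
injectEvents <- function(n, n_events, i_o = 220, sd = 2, ratio = 0.1,
                         tau = 50L, seed = 1L) {
  set.seed(seed)
  y <- rnorm(n, i_o, sd)
  slot_w <- n %/% (n_events + 2L)
  stopifnot(slot_w > tau + 2L)
  starts <- (seq_len(n_events)) * slot_w          # 0-based starts
  for (s in starts) y[(s + 1L):(s + tau)] <- rnorm(tau, ratio * i_o, sd)
  list(y = y, truth = data.frame(start = starts, end = starts + tau))
}

# Published oligo table used by the chromophore arithmetic checks:
# sequence, printed theoretical R(312/272) for T-only, and
# (observed R, printed average tags) pairs that are self-consistent at the
# printed precision.
oligoTable <- function() {
  list(
    theoretical = data.frame(
      id = c("PrimerM13for(-20)", "PrimerM13for(-41)", "PrimerM13rev(-27)",
             "PrimerM13rev(-48)", "BJ1", "BJ2", "BJ3", "BJ4",
             "ComplM13for(-20)", "BJ2TA(OMe)", "dmiR21", "21EXT",
             "dmiR122", "2XdmiR122", "122EXT", "dmiR140", "2XdmiR140",
             "140EXT(mU)", "21EXT(mU)", "BJ1EXT(mU)", "d(CT)10"),
      seq = c(
        "GTA AAA CGA CGG CCA GT",
        "CGC CAG GGT TTT CCC AGT CAC GAC",
        "CAG GAA ACA GCT ATG AC",
        "AGC GGA TAA CAA TTT CAC ACA GG",
        "CAG TCA CGA CGT TGT AAA ACG ACG GCC AGT",
        "GGG TAA CGC CAG GGT TTT CCC AGT CAC GAC",
        "GGG TAA CGC CAG GGT TTC CCC AGT CAC GAC",
        "GGG TAA CGC CAG GGT TTT TCC AGT CAC GAC",
        "TTG GCA CTG GCC GTC GTT TTA CAA CGT CGT GAC TG",
        "TTT CGC CAG GGU UUU CCC AGU CAC GAC AAA",
        "TCA ACA TCA GTC TGA TAA GCT A",
        "TTT CAA CAT CAG TCT GAT AAG CTA",
        "CAA ACA CCA TTG TCA CAC TCC A",
        "CAAACACCATTGTCACACTCCACAAACACCATTGTCACACTCCA",
        "TTT CAA ACA CCA TTG TCA CAC TCC A",
        "CTA CCA TAG GGT AAA ACC ACT G",
        "CTACCATAGGGTAAAACCACTGCTACCATAGGGTAAAACCACTG",
        "TTT CmUA CCA mUAG GGmU AAA ACC ACmU GAA",
        "TTT CAA CAmU CAG mUCmU GAmU AAG CmU AAA",
        "TTT GmUA AAA CGA CGG CCA GmUA AA",
        "CTCTCTCTCTCTCTCTCTCT"),
      printed = c(0.235, 0.417, 0.235, 0.348, 0.333, 0.400, 0.333, 0.467,
                  0.629, 0.200, 0.545, 0.667, 0.364, 0.364, 0.560, 0.364,
                  0.364, 0.222, 0.231, 0.261, 1.00)
    ),
    avg_osbp = data.frame(
      id = c("PrimerM13for(-20)", "PrimerM13rev(-27)", "PrimerM13rev(-48)",
             "PrimerM13for(-41)", "BJ1(o)", "BJ1(b)", "BJ2", "BJ3(o)",
             "BJ3(b)", "BJ4(o)", "BJ4(b)", "dmiR122", "2XdmiR122",
             "122EXT", "d(CT)10", "140EXT(mU)(a)", "140EXT(mU)(b)",
             "21EXT(mU)(a)", "BJ2TA(OMe)", "BJ2AT(OMe)", "BJ2EXT(mU)",
             "dmiR21(OMe)(b)", "ComplmiR21"),
      r_obs = c(0.230, 0.236, 0.326, 0.416, 0.295, 0.327, 0.401, 0.347,
                0.353, 0.452, 0.445, 0.404, 0.380, 0.602, 1.044, 0.374,
                0.314, 0.433, 0.324, 0.311, 0.278, 0.082, 0.183),
      nt = c(17L, 17L, 23L, 24L, 30L, 30L, 30L, 30L, 30L, 30L, 30L, 22L,
             44L, 25L, 20L, 27L, 27L, 27L, 30L, 30L, 30L, 22L, 22L),
      printed = c(1.955, 2.006, 3.749, 4.992, 4.425, 4.905, 6.015, 5.205,
                  5.295, 6.780, 6.675, 4.444, 8.36, 7.525, 10.44, 5.049,
                  4.239, 5.846, 4.860, 4.665, 4.170, 0.902, 2.013)
    )
  )
}

# the nine hybridization-tested probes and their observed outcomes
feasibilityTable <- function() {
  data.frame(
    id = c("BJ1", "BJ2", "BJ3", "BJ4", "dmiR122", "dmiR140", "2XdmiR122",
           "dmiR21", "21EXT"),
    seq = c("CAGTCACGACGTTGTAAAACGACGGCCAGT",
            "GGGTAACGCCAGGGTTTTCCCAGTCACGAC",
            "GGGTAACGCCAGGGTTTCCCCAGTCACGAC",
            "GGGTAACGCCAGGGTTTTTCCAGTCACGAC",
            "CAAACACCATTGTCACACTCCA",
            "CTACCATAGGGTAAAACCACTG",
            "CAAACACCATTGTCACACTCCACAAACACCATTGTCACACTCCA",
            "TCAACATCAGTCTGATAAGCTA",
            "TTTCAACATCAGTCTGATAAGCTA"),
    feasible = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

t8Sequence <- function()
  paste0(strrep("AG", 4), "CC", strrep("AG", 4), "CC", strrep("AG", 3),
         "CCUUCA")
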