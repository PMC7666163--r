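test_that("the oligo dialect parses and renders round-trip", {
  s <- nucleicSequence("TTT CmUA CCA mUAG GGmU AAA ACC ACmU GAA")
  expect_equal(length(s), 27L)
  expect_equal(sum(seqSugars(s) == "2OMe"), 4L)
  expect_equal(as.character(s), "TTTCmUACCAmUAGGGmUAAAACCACmUGAA")
  r <- nucleicSequence("UGG AGU", sugar = "ribo")
  expect_true(all(seqSugars(r) == "ribo"))
  expect_error(nucleicSequence("ACGX"), "unknown base")
  expect_error(nucleicSequence("ACm"), "trailing 'm'")
})

test_that("reverse complement matches the published probe and is an involution", {
  m122 <- nucleicSequence("UGG AGU GUG ACA AUG GUG UUU G", sugar = "ribo")
  expect_equal(as.character(reverseComplement(m122)),
               "CAAACACCATTGTCACACTCCA")
  set.seed(8)
  for (i in 1:10) {
    b <- sample(c("A", "C", "G", "T"), sample(5:40, 1), replace = TRUE)
    s <- nucleicSequence(paste(b, collapse = ""))
    twice <- reverseComplement(reverseComplement(s))
    expect_equal(seqBases(twice), seqBases(s))
  }
})

test_that("reverse complement agrees with Biostrings on plain DNA", {
  set.seed(9)
  for (i in 1:5) {
    sq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
    ours <- as.character(reverseComplement(nucleicSequence(sq)))
    ref <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    expect_equal(ours, ref)
  }
})

test_that("theoretical R(312/272) reproduces the published table", {
  tab <- oligoTable()$theoretical
  for (i in seq_len(nrow(tab))) {
    got <- theoreticalR(tab$seq[i])
    expect_equal(round(got, 3), round(tab$printed[i], 3),
                 info = tab$id[i], tolerance = 1e-3)
  }
  expect_equal(theoreticalR(strrep("A", 17)), 0)
})

test_that("theoretical R stays in [0, 2] and hits 2 only for all-pyrimidine", {
  expect_equal(theoreticalR("CTCTCTCTCT", mode = "all_pyrimidines"), 2)
  expect_lt(theoreticalR("ACTCT", mode = "all_pyrimidines"), 2)
  set.seed(10)
  for (i in 1:10) {
    sq <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                collapse = "")
    r <- theoreticalR(sq, mode = "all_pyrimidines")
    expect_gte(r, 0); expect_lte(r, 2)
  }
})

test_that("average tags from observed R reproduce the published table", {
  tab <- oligoTable()$avg_osbp
  for (i in seq_len(nrow(tab))) {
    got <- avgOsBpFromR(tab$r_obs[i], tab$nt[i])
    expect_equal(got, tab$printed[i], tolerance = 2e-3, info = tab$id[i])
  }
  expect_equal(avgOsBpFromR(0, 24), 0)
  expect_warning(avgOsBpFromR(1.9, 20, pyrimidineCount = 5), "exceeds")
})

test_that("R arithmetic inverts exactly on the pyrimidine count", {
  set.seed(11)
  for (i in 1:10) {
    sq <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1),
                       replace = TRUE), collapse = "")
    s <- nucleicSequence(sq)
    py <- sum(seqBases(s) %in% c("C", "T", "U"))
    expect_equal(avgOsBpFromR(theoreticalR(s, "all_pyrimidines"),
                              length(s)), py)
  }
})

test_that("osmylation kinetics: anchor, limits, monotonicity and ordering", {
  u <- nucleicSequence("U", sugar = "ribo")
  expect_equal(predictOsmylation(u, "c")$probabilities, 0.43)
  ## zero incubation time labels nothing
  p0 <- new("OsmylationProtocol", id = "t0", osbpMm = 2.6, timeMin = 0)
  mix <- nucleicSequence("ACGTU")
  expect_true(all(predictOsmylation(mix, p0)$probabilities == 0))
  ## purines never react
  pur <- predictOsmylation(nucleicSequence("AG"), "d")$probabilities
  expect_equal(pur, c(0, 0))
  ## monotone in time and concentration
  proto <- function(mm, t) new("OsmylationProtocol", id = "x",
                               osbpMm = mm, timeMin = t)
  pU <- function(mm, t)
    predictOsmylation(u, proto(mm, t))$probabilities
  expect_true(all(diff(sapply(c(10, 30, 60, 120), function(t) pU(2.6, t)))
                  > 0))
  expect_true(all(diff(sapply(c(1, 2.6, 3.9, 5.25), function(m) pU(m, 30)))
                  > 0))
  ## base ordering at equal conditions: T/5-MeU > U > C
  s <- nucleicSequence("mTmUmC")    # all on the ribo scale via 2'-OMe
  p <- predictOsmylation(s, "c")$probabilities
  expect_true(p[1] > p[2] && p[2] > p[3])
  dna <- predictOsmylation(nucleicSequence("TUC"), "b")$probabilities
  expect_true(dna[1] > dna[2] && dna[2] > dna[3])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("expected tags on the long RNA: U component follows the 0.43 slope", {
  rna100 <- paste0(
    "UUACAGCCACGUCUACAGCAGUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGG",
    "CUAGUCCGUUAUCAACUUGAAAAAGUGGCACCGAGUCGGUGCUUUU")
  s <- nucleicSequence(rna100, sugar = "ribo")
  expect_equal(length(s), 100L)
  nU <- sum(seqBases(s) == "U")
  p <- predictOsmylation(s, "c")
  expect_equal(sum(p$probabilities[seqBases(s) == "U"]), 0.43 * nU,
               tolerance = 1e-9)
  ## full expectation adds the (slower) C contribution on top
  nC <- sum(seqBases(s) == "C")
  expect_gt(p$expectedOsBp, 0.43 * nU)
  expect_lt(p$expectedOsBp, 0.43 * nU + 0.12 * nC)
})

test_that("kinetic model predicts the observed tag counts of extended probes", {
  ## published averages: 4.644 (21EXT(mU), protocol b), 4.239 (140EXT(mU), b)
  p21 <- predictOsmylation("TTT CAA CAmU CAG mUCmU GAmU AAG CmU AAA", "b")
  expect_equal(p21$expectedOsBp, 4.644, tolerance = 0.05)
  p140 <- predictOsmylation("TTT CmUA CCA mUAG GGmU AAA ACC ACmU GAA", "b")
  expect_equal(p140$expectedOsBp, 4.239, tolerance = 0.05)
})

test_that("topoisomer sampler matches the per-position probabilities", {
  s <- nucleicSequence("UCUCUCUCUC", sugar = "ribo")
  m <- sampleTopoisomers(s, "c", n = 4000L, seed = 42L)
  p <- predictOsmylation(s, "c")$probabilities
  expect_equal(colMeans(m), p, tolerance = 0.05)
  expect_identical(m, sampleTopoisomers(s, "c", n = 4000L, seed = 42L))
})

test_that("probe designs reproduce the published probes", {
  d122 <- designProbe("UGG AGU GUG ACA AUG GUG UUU G",
                      mode = "plain_complement")
  expect_equal(as.character(probeSeq(d122)), "CAAACACCATTGTCACACTCCA")
  expect_equal(complementaryRegion(d122), c(1L, 22L))

  d140 <- designProbe("CAG UGG UUU UAC CCU AUG GUA G", tails = c(3L, 2L))
  expect_equal(as.character(probeSeq(d140)),
               "TTTCmUACCAmUAGGGmUAAAACCACmUGAA")
  expect_equal(complementaryRegion(d140), c(4L, 25L))
  expect_equal(taggedPositions(d140), 1:3)   # protocol b tags the dT tail
  expect_error(designProbe(""), "empty")
})

test_that("the complementary region of any design pairs the target exactly", {
  set.seed(12)
  for (i in 1:8) {
    tgt <- paste(sample(c("A", "C", "G", "U"), sample(15:30, 1),
                        replace = TRUE), collapse = "")
    d <- designProbe(nucleicSequence(tgt, sugar = "ribo"))
    region <- complementaryRegion(d)
    sub <- seqBases(probeSeq(d))[region[1]:region[2]]
    sub[sub == "U"] <- "T"     # mU pairs like T
    expected <- seqBases(reverseComplement(targetSeq(d)))
    expect_equal(sub, expected)
    sc <- duplexScore(probeSeq(d), targetSeq(d))
    expect_gte(sc$maxPairs, region[2] - region[1] + 1L)
  }
})

test_that("duplex scoring: published pairing, identity and degenerate cases", {
  sc <- duplexScore(t8Sequence(), strrep("CT", 10))
  expect_equal(sc$maxPairs, 16L)
  expect_equal(sc$gcPairs, 8L)
  ## symmetric in its arguments
  sc2 <- duplexScore(strrep("CT", 10), t8Sequence())
  expect_equal(sc2$maxPairs, 16L)
  expect_equal(sc2$gcPairs, 8L)
  ## a sequence against its exact reverse complement pairs fully
  s <- "GATTACAGGCAT"
  expect_equal(duplexScore(s, as.character(reverseComplement(s)))$maxPairs,
               nchar(s))
  expect_equal(duplexScore(strrep("A", 10), strrep("C", 10))$maxPairs, 0L)
})

test_that("feasibility classifies all nine hybridization-tested probes", {
  tab <- feasibilityTable()
  for (i in seq_len(nrow(tab))) {
    f <- hybridizationFeasibility(tab$seq[i])
    expect_equal(f$feasible, tab$feasible[i], info = tab$id[i])
  }
  ## the published run lengths for the two flagship cases
  expect_equal(hybridizationFeasibility("TCAACATCAGTCTGATAAGCTA")$longestRun,
               5L)
  expect_equal(
    hybridizationFeasibility("CAGTCACGACGTTGTAAAACGACGGCCAGT")$longestRun,
    14L)
  ## untagged probe: run spans the whole region
  f <- hybridizationFeasibility("CAGCAGCAG", taggedPositions = integer())
  expect_true(f$feasible)
  expect_equal(f$longestRun, 9L)
})

test_that("voltage recommendation follows the tag layout", {
  ## 122EXT: 5' TTT tail -> 3 adjacent tags -> -210 mV
  v <- recommendVoltage("TTTCAAACACCATTGTCACACTCCA")
  expect_equal(v$voltageMv, -210L)
  ## all-2'-OMe probe, protocol d: scattered U tags -> -180 mV
  d21 <- nucleicSequence("UCAACAUCAGUCUGAUAAGCUA", sugar = "2OMe")
  tags <- predictTaggedPositions(d21, protocol = "d")
  expect_true(length(tags) > 0 && all(diff(sort(tags)) > 1L))
  v2 <- recommendVoltage(d21, taggedPositions = tags)
  expect_equal(v2$voltageMv, -180L)
  ## untagged oligo is undetectable
  v3 <- recommendVoltage("CAGCAGCAG", taggedPositions = integer())
  expect_false(v3$detectable)
  expect_true(is.na(v3$voltageMv))
})

test_that("osmylation protocols carry the published constants", {
  expect_equal(osmylationProtocol("b")@osbpMm, 2.6)
  expect_equal(osmylationProtocol("b")@timeMin, 30)
  expect_equal(osmylationProtocol("c")@osbpMm, 3.9)
  expect_equal(osmylationProtocol("a")@timeMin, 45)
  expect_equal(osmylationProtocol("d")@osbpMm, 5.25)
  ## relative reactivities: T/dC = 28, dU/dC = 3.75, hence T/dU = 7.5 (printed)
  sc <- reactivityScale()
  expect_equal(round(sc@ratesDeoxy[["T"]] / sc@ratesDeoxy[["U"]], 1), 7.5)
  expect_equal(sc@ratesRibo[["U"]], 4.7)
  expect_equal(sc@ratesRibo[["T"]], 44)
})
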