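---
title: "Counting osmylated probes on nanopore arrays: methods and design notes"
author: "poretag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting osmylated probes on nanopore arrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretag)
```

## The assay in one paragraph

A commercial nanopore flow cell applies a constant negative potential across
an array of protein pores (512 monitored channels on a full array, 126 on the
small one) and records each channel's ionic current at 3.012 kHz — three data
points per millisecond. An unoccupied pore passes a stable open current
$I_o$; a translocating molecule reduces it to a residual current $I_r$ for a
residence time $\tau$. Native short DNA/RNA traverses in microseconds and is
essentially invisible at this acquisition rate. A complementary probe
carrying bulky osmium tetroxide–bipyridine (OsBp) tags on its pyrimidines
translocates slowly enough to register as a discrete blockade, so its
passages can be *counted*. When the probe's target is present, probe and
target form a 1:1 duplex too wide for the pore: the probe's counts collapse
("silencing"). Comparing a probe-only count to a probe-plus-sample count
therefore reads out presence or absence of the target, down to attomole
loads. This package implements the event-detection pipeline, the counting
and decision rules, the probe-design calculators, and a simulator that
generates traces with known ground truth.

## Event detection

Let $y$ be one channel's ordered current samples. The pipeline has three
stages.

**Baseline.** The open-current baseline is the median of samples strictly
inside a window $(o_{low}, o_{up})$:
$b_o = \mathrm{med}\{i \in y : o_{low} < i < o_{up}\}$. When the window is
not supplied, it is estimated per trace as the mode of a 1-pA histogram of
the samples $\pm\,25\,\sigma_{rough}$, where $\sigma_{rough}$ is the
standard deviation of the central 50% of samples (floored at 0.1 pA so a
constant trace still yields a valid window). The mode-based center is robust
because the open-pore level dominates any realistic trace; the wide
$\pm 25\sigma$ margin only needs to exclude in-event samples, which sit at a
fraction of $b_o$.

**Noise.** The trace is split into consecutive segments of
`segmentSize` samples (default 100,000; the last segment may be short) and
the standard deviation of in-window samples is computed per segment. The
channel noise $\sigma_o$ is by default the *median* of the per-segment
values, which is robust to event-dense segments; `noiseMode = "global"`
computes one standard deviation over all in-window samples instead. The
per-segment values double as a quality-control metric: a channel whose
per-segment noise varies by more than `qcSdFactor` (default 3, max/min) is
flagged as having an unstable baseline. A channel with no in-window samples
at all (a blocked or dead pore) fails QC outright and contributes zero
events rather than an error in multi-channel runs.

**Threshold, candidates, filters.** The detection threshold is
$b_{all} = b_o\,(1 - k\,\sigma_o/b_o) = b_o - k\,\sigma_o$ with $k = 10$ by
default. Candidate events are maximal runs of consecutive samples strictly
below $b_{all}$; with the default `baselineMode = "segment"`, $b_o$ and
$b_{all}$ are recomputed per segment and candidates are scored against a
per-sample step function, so an event crossing a segment boundary is not
split. Runs touching the first or last sample are flagged truncated and
excluded (their true duration and minimum are unknown). A candidate
$[\tau_1, \tau_2)$ is accepted iff

$$t_{min} \le \tau_2 - \tau_1 \le t_{max}
\quad\text{and}\quad
b_{min} \le \frac{\min(y_{\tau_1:\tau_2})}{b_o} \le b_{max}.$$

The working settings are $4 \le \tau \le 300$ data points (1.3–100 ms) and
$\min(I_r)/b_o \le 0.55$. The defining formulas use strict inequalities
while the settings actually used are inclusive; `inclusiveBounds = TRUE`
(default) matches the settings, and strict mode is available. Runs separated
by even a single above-threshold sample remain distinct events: the parser
is a single-threshold scan with no hysteresis or merging, which suffices
because OsBp blockades are deep (tens of $\sigma_o$) and transitions are
sharp.

Accepted events report $I_r$ as the in-event *minimum* current — the
quantity the ratio filter uses — plus an informational in-event mean. The
filter depends only on $\min(y)/b_o$, so detection is equivariant under
rescaling of the current axis: multiplying all samples and both window
bounds by any $c > 0$ leaves indices and ratios unchanged (verified by
property test).

## Counting, outliers, and the silencing decision

Accepted events are binned by $I_r/I_o$ with a 0.05-wide histogram
(left-closed bins tiling $[0, b_{max}]$, last bin closed so a ratio exactly
at the bound is counted). The modal bin midpoint, $(I_r/I_o)_{max}$, is the
fingerprint of a species — about 0.1 for heavily tagged probes.

Working pores typically agree in counts within a factor of 5; a small
fraction (about 2.5%) record markedly higher counts. A channel is flagged as
an outlier when its count exceeds `outlierFactor` (default 5) times the
median nonzero per-channel count. Outliers are reported but *included* in
totals by default, matching how the assay's totals are quoted; excluding
them changes counts but not conclusions.

The presence/absence call compares a probe-only count $P$ to a
probe-plus-sample count $M$: the target is called **present** when
$P \ge 3M$ — the proposed lower detectability limit — and **absent**
otherwise. A buffer-control count, when available, may be subtracted from
both (floored at zero) before the ratio; the rule's original statement does
not fix whether subtraction precedes the ratio, so both forms are exposed
and the unsubtracted form is the default. If the adjusted probe count is
zero the probe itself was undetectable and the call is *indeterminate*; if
only the adjusted mixture count is zero the call is *present*.

Quantification is deliberately one-sided: proportionality between counts and
concentration was not established for this platform, so a present call
bounds the target at or above the known probe load (1:1 hybrid), an absent
call bounds it below, and the suggested follow-up moves the probe load by a
factor of 5 — a geometric search whose bracket carries roughly 30% accuracy.

## Probe design calculators

**Sequences.** Probes mix chemistries: deoxy residues, ribo residues and
2′-O-methyl residues (written `mU` etc. in the compact dialect this package
parses). A T nucleobase on a ribose or 2′-OMe sugar is the 5-methyl-U
equivalent.

**Chromophore arithmetic.** The OsBp adduct absorbs near 312 nm where
nucleic acids do not, giving the quality-control ratio
$R(312/272) = 2 \times (\text{tagged pyrimidines})/(\text{total nt})$,
hence an average tag count of $R_{obs} \times nt/2$ from an observed ratio.

**Kinetics.** Osmylation is run with a 20-fold reagent excess, so
per-position labeling follows pseudo-first-order kinetics:
$P_j = 1 - \exp(-r_{ref}\, \rho_j\, C\, t)$ with relative rates $\rho$ per
nucleobase (deoxy scale: T = 28, dU = 3.75, dC = 1; ribo scale:
5-MeU = 44, U = 4.7, C = 1; purines 0 — the sugar and backbone contribute
negligibly, so the nucleobase selects the rate and the sugar selects the
scale). Only relative rates are published; the absolute constant
$r_{ref}$ is anchored so that U under protocol c (30 min, 3.9 mM) labels
with probability 0.43, the observed slope of average tags per molecule
against U count. The expected tags per molecule is $\sum_j P_j$. Note the
anchored slope empirically absorbs the small C contribution
($P_C \approx 0.11$ under protocol c), so the kinetic sum sits slightly
above $0.43 \times \#U$ for C-containing oligos; on T-containing extended
probes under protocol b the sum reproduces the observed averages within a
few percent (e.g. predicted 4.62 vs observed 4.644 tags for a 27-nt
extended probe).

**Tag placement.** Protocol b tags practically 100% of Ts and little else,
so for T-containing probes the predicted tag positions are exactly the T
positions; for T-free probes, positions with $P_j \ge 0.5$ under the
supplied protocol are used, and a seeded Bernoulli sampler
(`sampleTopoisomers()`) draws per-molecule tag patterns for topoisomer
mixtures.

**The extended-mU design.** The general probe design for an arbitrary
target is: reverse complement of the target with every internal T replaced
by 2′-OMe-U (keeping A:U pairing while minimizing internal tagging), three
dT residues prepended at the 5′ end (a deliberate tag cluster), and two to
three dA residues appended at the 3′ end to ease pore entry. When the
complement itself begins with T adjacent to the new tail the generator does
not merge them; the published 27-nt variant of one such probe is one
residue shorter than the stated rules produce, an edit we treat as manual.

**Feasibility.** Hybridization fails when many single tags are spread
across the complementary region and succeeds when tags cluster, leaving a
long untagged stretch free to pair. The rule: compute the longest
contiguous untagged run within the complementary region; feasible iff the
run reaches `runMin = 8`. Probes observed not to hybridize have runs of at
most 5; probes observed to hybridize have runs of at least 8 — 8 is the
smallest separating value, and the parameter is configurable precisely
because it is calibrated on nine probes.

**Duplex scoring and voltage.** `duplexScore()` does an exhaustive ungapped
antiparallel offset scan counting Watson–Crick pairs (A·T, A·U, G·C); no
G·U wobble is allowed, which exactly reproduces the published 16-of-20
pairing (8 G·C) between the partially complementary control pair. Probes
with three or more adjacent tags need about −210 mV to translocate; probes
with scattered tags run at −180 mV; untagged oligos are undetectable. The
−180/−210 mV split is itself useful: non-target material can be depleted at
−180 mV before raising the voltage to count the probe.

## The simulator

`simulateExperiment()` generates per-channel traces as Gaussian open-pore
current (defaults: 220 pA, 2 pA noise, 3012 Hz) with rectangular blockades
injected at Poisson arrival times, uniformly placed without overlap and
never touching the trace boundary. Durations are log-normal (the
heavy-tailed shape typical of dwell times), clipped to one sample. Each
event's depth parameter sets its *minimum* residual current — the statistic
the detector reports — with baseline-sized noise riding above that floor;
this makes planted and detected ratios directly comparable and avoids the
systematic $\sim 2\sigma$ downward bias a mean-parameterized rectangle
would show in the min statistic.

Species defaults are the assay's operating conditions: the probe blocks at a depth
centered on 0.12 (so the detected modal 0.05-bin is $[0.10, 0.15)$, the
observed $(I_r/I_o)_{max} \approx 0.1$ peak), dwells tens of data points,
and is voltage-gated at 200 mV magnitude (the −180 vs −210 mV behaviour of
tail-tagged probes); its rate, 0.056 Hz per channel, yields on the order of
$10^5$ events for a 1-h, ~500-channel run, matching quoted totals. The
hybrid regime is the probe rate divided by 20. Buffer background runs at
0.0042 Hz per channel, the rate implied by a quoted ~7,680-count, ~1-h
control test on a full array. Intact oligos arrive at 0.05 Hz but with a
dwell median of 0.5 samples — translocation of a ~20-nt oligo takes
microseconds, far below the 0.33-ms sample interval — so nearly all
arrivals are invisible and detected counts stay comparable to buffer. A
seeded 2.5% of channels are planted as outliers with all rates multiplied
by 10. Everything is deterministic given the seed and channel id.

What the simulator does *not* emulate: sub-event current structure, pore
aging and replacement over a run, rate heterogeneity beyond the outlier
mechanism, voltage-dependent capture kinetics, and the composition of real
buffer events. Passing tests on synthetic data therefore validate the
segmentation, filtering, counting and decision logic under the stated
generative assumptions — not the biophysics of any particular flow cell.

## Numerical choices and degenerate inputs

* Indices are 0-based half-open $[\tau_1, \tau_2)$ with
  $\tau = \tau_2 - \tau_1$, so the minimum accepted $\tau$ of 4 means four
  samples inside the event.
* Candidate detection uses strict `<` against the threshold; filter windows
  are inclusive by default (see above).
* Histogram bins are left-closed, last bin right-closed; modal-bin ties
  resolve to the lowest bin.
* A trace shorter than one segment is its own (short) segment; segments
  without enough in-window samples inherit the channel-level baseline and
  threshold.
* Blocked-pore traces (no in-window samples) fail QC quietly in
  multi-channel runs; a threshold at or below zero current raises a
  configuration error, since it can never be crossed.
* Event simulation with more event mass than trace length raises a packing
  error rather than silently overlapping events; rare cross-species
  collisions are resolved by dropping the later arrival and restoring the
  trace so the truth table always matches the samples.
* Problem sizes in the shipped tests — traces of $10^5$–$10^6$ samples,
  4–8 channels, 10–20 seeds per property — were chosen so each property is
  measured on hundreds of events or tens of millions of noise samples,
  which keeps the binomial/Poisson uncertainty of every pass/fail margin
  far from its threshold.

## Known limitations

* The feasibility threshold (`runMin = 8`) is calibrated on the nine probes
  with documented hybridization outcomes; sequences near the boundary
  deserve a wet-lab check.
* The kinetic calibration rests on a single anchored slope; protocol o
  (reagent prepared without pre-dissolving bipyridine) is known to be less
  potent, and no separate potency factor is applied to it.
* Quantification is one-sided by design; absolute target concentration
  requires the iterative load search.
* Bulk fast5 reading targets the standard bulk-raw layout
  (`/Raw/Channel_<id>/Signal`); single-read fast5 variants are out of
  scope, and a per-channel CSV path is provided as the portable fallback.
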