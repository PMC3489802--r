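---
title: "Recurrently altered region discovery and prognostic marker mining: methods"
author: "rarseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrently altered region discovery and prognostic marker mining: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`rarseek` implements a complete cohort analysis for array-CGH copy-number
profiles of tumors: per-sample segmentation of probe-ordered log2
tumor/reference ratios, categorical copy-number calling, delineation of
recurrently altered regions (RARs) across the cohort, stage-based
classification of RARs as earlier or later events in tumor progression,
CPAR-style mining of marker combinations predicting death, and survival
analysis (Kaplan–Meier, log-rank, Cox) of single and combined markers.
A replication arm quantifies targeted loci by genomic qPCR
(delta-delta-Ct) and reruns the survival battery on the resulting binary
gain calls.

Inputs are assumed to be normalized log2 ratios on a fixed probe map
(chromosomes 1–22 and X, one representative coordinate per probe,
1-based inclusive bp internally; report tables print megabases with two
decimals). Missing ratio values are carried as `NA` and excluded
probe-wise from all statistics; a missing probe inherits the state of
its enclosing segment for reporting. Tables are tab-separated UTF-8 with
headers; segments use a SEG-style layout because it is the de-facto
interchange format for copy-number segments. GEO SOFT parsing is out of
scope: users pre-convert series data to the TSV layout.

## Segmentation

Each chromosome is first cut into *runs* at gaps where adjacent probes
lie more than `max_probe_spacing` (default 1000 kbp) apart. Within a
run, segmentation is recursive binary splitting on the Wilcoxon
rank-sum statistic: for every admissible split (both sides at least
`min_probes` = 5 probes) we compute the standardized rank-sum statistic
of left versus right (midranks for ties; the empirical rank variance,
which equals the exact tie-corrected permutation variance), take the
maximal |Z| over splits, and assess it against a within-run label
permutation null (up to `max_permutations` = 10,000 draws). A split is
accepted when the permutation p-value `(b+1)/(B+1)` is below
`significance_threshold` (default 5.0e-4); accepted splits recurse into
both children. Segment means are arithmetic means of member values.

The commercial "rank segmentation" algorithm whose parameters this
procedure adopts does not disclose its internal test or stopping rule;
this is a re-specification in the same statistic family, honoring the
four published parameters, not a clone. Three numerical choices matter:

* **Determinism.** Argmax ties break to the leftmost split. Every
  tested node derives its own RNG seed from (seed, sample index, node
  offset, node length), so the permutation stream at a node does not
  depend on how many draws other nodes consumed. A consequence worth
  stating: lowering the significance threshold can never increase the
  number of segments on fixed data and seed.
* **Early stopping.** Permutations for a node stop as soon as the
  exceedance count makes `p >= threshold` certain; this cannot change
  any accept/reject decision, only the resolution of reported
  non-significant p-values.
* **Degenerate runs.** Runs shorter than `min_probes` are emitted as
  single segments flagged `"short"`; a constant run has statistic 0 and
  is never split.

Binary recursive splitting is less sensitive to a *short, centered*
plateau than two-boundary scan statistics (the single-split statistic
of a centered block is not extreme under permutation until the block is
reasonably wide). At the default whole-genome density (~24,000 probes)
the published minimum of 5 probes corresponds to well under 1 Mb and
implanted lesions of a few Mb are recovered exactly; sparse custom
layouts should keep lesions at a few dozen probes. Note also that
layouts sparser than ~1 probe/Mb interact with the 1000 kbp spacing
rule: every probe becomes its own flagged run, which is almost never
what the user wants.

## Copy-number calling

Segment means are thresholded exactly as the parameter phrasing
dictates: gains are strictly above +0.2 log2, losses strictly below
−0.3; high-level amplification is ≥ +1.5 (inclusive) and homozygous
deletion ≤ −1.5 (inclusive). Per-sample burden summaries count
non-neutral segments and sum their genomic extent; the denominator of
the altered fraction is the probe-map span (the published 13% figure
never states its denominator, so we use the quantity the data defines).

## RAR detection and event timing

Per-probe gain and loss frequencies are computed independently
(a probe's states partition, so gain + loss frequency is bounded by 1).
Candidate regions are maximal probe runs with frequency ≥ 30%
(inclusive); adjacent runs separated by even a single sub-threshold
probe are not merged, for determinism. Significance is assessed against
a permutation null in which each sample's within-chromosome state
vector is circularly shifted by a uniform offset. This preserves each
sample's segment-length spectrum and alteration burden — the key
confounder for recurrence — while destroying cross-sample alignment;
the p-value is the fraction of 1000 seeded permutations whose maximum
frequency over the candidate's span reaches the observed maximum.
Regions with p < 0.05 are reported, named RAR-G1… / RAR-L1… in genomic
order. The published analysis's own recurrence test is undisclosed;
the circular-shift null is this package's declared substitute.

A sample scores positive for a RAR (marker coding 0/1) when its
same-direction calls cover at least 50% of the RAR span; the source
analysis never states its scoring rule, and 50%-of-span is the middle
ground between any-overlap (too permissive for wide RARs) and
full-cover (too strict at segment boundaries). Reported RAR frequency
columns are recomputed from this marker matrix, so the printed
frequencies and the mining input are always consistent.

Event timing uses the only numeric anchors the source results give:
*earlier* if both stage-I and stage-II frequencies are ≥ 30%, *later*
if the stage-I frequency is strictly below 10% while stage II is
strictly above 40%, otherwise unclassified. This rule reproduces the
published 23-row table exactly (15 earlier / 2 later / 6 unclassified).
High-level regions are maximal runs carried by at least one sample,
reported when the carrier fraction strictly exceeds 10%, with
percentages rounded half away from zero (12.5% prints as 13, matching
the published counts).

## Rule mining (CPAR with Laplace accuracy)

Markers are mined against the binary survival class (0 = dead within
the horizon, 1 = alive) with a CPAR-family procedure: greedy FOIL-gain
literal selection on weighted examples, branching on every literal
whose gain is within `gain_similarity` = 0.99 of the best, stopping a
rule when no literal gains at least `min_gain` = 0.7 or no negative
example remains. After each rule the weights of covered positive
examples decay by 2/3; mining stops when remaining positive weight
falls below 5% of its initial total. These hyperparameters are the
algorithm's published defaults — the source analysis states none — and
all are exposed in `cpar_params()`. Literals are positive
(`marker = 1`) by default, since presence of an alteration is the
biologically meaningful predictor; `marker = 0` literals are a switch.

Weighting drives the *search only*: every reported rule carries exact
support counts recounted on the raw matrix, and rules are ranked by
Laplace accuracy `(N_c + 1)/(N_total + m)` with deterministic
tie-breaks (smaller antecedent, then lexicographic). Reported
death-associated combinations are rules predicting class 0 with Laplace
accuracy strictly above 0.75.

**Known limitation.** Greedy FOIL-gain search does not guarantee the
globally Laplace-optimal antecedent. On adversarial small instances the
optimum may only be reachable through a literal whose gain falls below
0.7 at some step, or a dominant class can make every literal's gain
negative so that no rule is emitted; in internal checks the best mined
rule matches exhaustive enumeration (antecedents up to size 3) on
roughly nine of ten random 12-sample instances, and almost always when
the optimum lies above the 0.75 reporting cutoff. Planted strong
marker–outcome structure of the kind the miner exists to find is
recovered reliably.

## Survival and association statistics

Standard models are delegated to base R and the survival package behind
the module surface: two-sided Fisher exact tests (stage collapsed to
I vs II, all clinical variables binary), Benjamini–Hochberg FDR across
the marker × variable family, Kaplan–Meier curves, log-rank tests, and
Cox proportional-hazards regression with **Breslow** tie handling — the
default of the statistical suite the source analysis used — adjusted
for age (<50 vs ≥50), stage, ER, PR and HER2. The event is death within
ten years of diagnosis; survivors and later deaths are censored at
min(follow-up, 10). Wald 95% intervals and p-values are reported;
constant covariates are dropped with a warning and a monotone partial
likelihood (|β| diverging) is an error naming the covariate rather than
a silently absurd hazard ratio. The three-level neither/either/both
grouping of a marker pair is compared with a log-rank trend test using
equally spaced scores (the linear combination of the observed-minus-
expected vector with its permutation covariance).

Molecular subtype is the total function of receptor status: hormone
receptor positive (ER and/or PR) maps to Luminal A (HER2−) or Luminal B
(HER2+); receptor-negative maps to HER2 (HER2+) or TNBC (all negative).

## qPCR replication

Relative dosage uses the pure delta-delta-Ct contrast: replicate Cts
are averaged first (the conventional mean-Ct-first aggregation; the
alternative, averaging per-run ratios, is not used), then
`ddCt = (Ct_target − Ct_control)_tumor − (Ct_target − Ct_control)_ref`
and dosage ratio `E^{-ddCt}` with amplification efficiency E fixed at
2.0 (an efficiency parameter exists but the method as named does not
efficiency-correct). A gain requires the ratio *strictly above* 2.0 —
the boundary case ratio = 2.0 is deliberately not a gain, and a
double-difference is invariant to any constant Ct shift (e.g. halving
template input). Replicate spreads above a configurable SD (0.5 cycles)
flag the call without dropping it.

## The synthetic cohort generator

The generator is first-class, tested code; it defines the conditions
under which every downstream claim is verified. Defaults emulate the
discovery-cohort structure: 48 samples of which 11 are stage I, ~24,000
probes laid out evenly over chromosomes 1–22 and X proportionally to
chromosome length, per-probe Gaussian noise of 0.15 log2 units, and
implant means +0.58 (gain), −1.0 (loss), ±1.8 (high-level). The noise
and mean levels are plausible for microdissected tumors of >60% tumor
cell content rather than calibrated to any dataset; cellularity
attenuation, dye bias, GC waves and spatial artifacts are deliberately
not simulated, so passing tests demonstrate algorithmic correctness on
clean segment-level signal, not robustness to platform artifacts.
The X chromosome is simulated like an autosome (female reference).

Carrier assignment is stratified by stage so stage-specific frequencies
are exact ("exact" quota mode, used whenever a frequency threshold must
behave deterministically) or binomial ("binomial" mode). Survival is
exponential with hazard `baseline_hazard` (default 0.025/year, giving
the ~20% ten-year event fraction typical of early-stage disease) times
the product of per-implant hazard multipliers; an `interactions` hook
multiplies the hazard further for samples carrying *all* implants of a
named set, which is how a synergistic double-positive effect (the
combined-marker hazard ratio) is planted. Administrative censoring at
10 years. Overlapping implants of opposite sign in the same sample are
refused — the implanted truth would be ambiguous. A Weibull shape hook
was considered and left out: the exponential model is the simplest
generator consistent with a proportional-hazards analysis.

## Problem sizes used by the test suite

Verification batteries choose sizes that keep the full suite fast while
preserving the claims being tested: split-vs-exhaustive comparisons use
runs of ≤ 50 probes against an independently coded rank-statistic
oracle; null calibration segments 11 no-implant samples at the full
24,107-probe layout across 20 generator seeds (at most one non-neutral
call per sample is tolerated, mirroring normal-to-normal calibration);
zero-noise implant recovery runs a 16-sample full-layout cohort and
requires probe-exact RAR bounds; Cox recovery fits 100 replicate
cohorts of n = 300 with a true combined-marker hazard ratio of 7.31
and requires ≥ 90 of 100 Wald intervals to cover the truth; end-to-end
pipeline tests use a 48-sample, 6,000-probe layout with a
2,000-permutation budget. Fisher, FDR, Kaplan–Meier, log-rank, Cox and
delta-delta-Ct each have closed-form or enumeration oracles computed by
hand in the test helpers.

## Interfaces

The package's functions are the interface: `simulate_cohort()`,
`segment_cohort()`, `call_segments()`, `detect_rars()`,
`detect_high_level()`, `marker_matrix()`, `mine_rules()`,
`report_death_rules()`, the clinical-statistics functions, and the two
orchestrators `run_discovery()` / `run_replication()` whose reports
carry a provenance block (parameters, seed, package version) making
every number recomputable. A separate shell CLI and YAML run-configs
were considered and dropped: an R call is the configuration, and the
orchestrators log per-stage record counts to the message stream.
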