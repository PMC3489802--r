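# rarseek

Cohort-scale discovery of recurrent somatic copy-number alterations and
prognostic marker combinations from array-CGH profiles.

## The problem

Array comparative genomic hybridization measures, for every probe `j`
of a genome-wide layout, the log2 ratio of tumor to normal reference
DNA. Somatic copy-number alterations (CNAs) appear as contiguous probe
segments with a shifted mean. For a cohort of tumors the questions are:
which genomic regions are altered *recurrently* (more often than the
samples' own alteration burden explains), which of those recur early
versus late in tumor progression, and which single regions — or
combinations of regions — predict patient survival. `rarseek`
implements that full analysis for early-stage breast cancer style
cohorts, plus a qPCR-based replication arm, and ships a synthetic
cohort generator so everything is testable without patient data.

## The method

* **Segmentation.** Per sample, chromosomes are split into runs at
  probe gaps > 1000 kbp, then recursively partitioned by binary
  splitting on the standardized Wilcoxon rank-sum statistic; a split is
  accepted when its within-run permutation p-value is below `5.0e-4`
  and both children have ≥ 5 probes.
* **Calling.** Segment means above +0.2 log2 are gains, below −0.3
  losses; ≥ +1.5 / ≤ −1.5 additionally flag high-level amplification /
  homozygous deletion.
* **Recurrently altered regions (RARs).** Maximal probe runs where the
  gain (or loss) frequency is ≥ 30% of samples, kept when a
  circular-shift permutation null (preserving each sample's segment
  length spectrum) gives p < 0.05. RARs frequent (≥ 30%) in both stage
  I and stage II are classified *earlier* events; those at < 10% in
  stage I but > 40% in stage II are *later* events.
* **Rule mining.** Binary RAR markers versus survival status are mined
  CPAR-style (greedy FOIL-gain growth with example-weight decay);
  rules are ranked by Laplace accuracy `(N_c + 1)/(N_total + m)` and
  death-predicting rules with accuracy > 0.75 are reported.
* **Survival.** Kaplan–Meier curves, log-rank (and trend) tests, and
  Cox proportional-hazards regression (Breslow ties; Wald 95% CIs)
  adjusted for age, stage, ER, PR and HER2, with the event defined as
  death within ten years. Combined markers are conjunctions
  (`both = marker_A AND marker_B`).
* **qPCR replication.** Locus dosage by delta-delta-Ct against a
  diploid control locus, `ratio = 2^-ddCt`, gain iff ratio strictly
  above 2; the survival battery then runs on the binary calls.

See `vignettes/rarseek-methods.Rmd` for assumptions, parameter
semantics, numerical choices and limitations.

## Worked example

Simulate a 48-sample cohort (11 stage I) with two implanted gains
(chr16, chr17) whose co-occurrence multiplies the event hazard by 8,
and one implanted loss (chr8); then run the discovery pipeline:

```r
library(rarseek)

imps <- list(
  implant_spec("16", 20e6, 50e6, "gain", freq_stageI = 0.4, freq_stageII = 0.4),
  implant_spec("17", 10e6, 45e6, "gain", freq_stageI = 0.4, freq_stageII = 0.4),
  implant_spec("8",  5e6,  35e6, "loss", freq_stageI = 0.5, freq_stageII = 0.5))
cfg <- cohort_config(n_samples = 48, n_stageI = 11, probe_count = 6000,
                     noise_sd = 0.12, implants = imps,
                     interactions = list(list(implants = c(1, 2),
                                              hazard_multiplier = 8)),
                     baseline_hazard = 0.02, carrier_mode = "exact",
                     seed = 61)
sim <- simulate_cohort(cfg)
report <- run_discovery(sim$probes, sim$ratios, sim$clinical,
                        seg = seg_params(seed = 3, max_permutations = 2000),
                        n_perm = 199, seed = 3)
```

The RAR table recovers the three implants with their stage-stratified
carrier frequencies and event class:

```
    name chrom size_mb type p_value freq_total freq_stageI freq_stageII   event
1 RAR-G1    16    30.0 gain   0.005      0.396       0.364        0.405 earlier
2 RAR-G2    17    35.0 gain   0.005      0.396       0.364        0.405 earlier
3 RAR-L1     8    29.6 loss   0.005      0.521       0.545        0.514 earlier
```

The mined death rules contain the planted lethal pair — every reported
rule includes both `RAR-G1=1` and `RAR-G2=1` — with exact support
counts (`n_c` of `n_total` rule-satisfying patients died):

```
                      antecedent class n_total n_c laplace
1 RAR-G1=1 & RAR-G2=1 & RAR-L1=1     0       5   5   0.857
2            RAR-G1=1 & RAR-G2=1     0       9   8   0.818
```

and the covariate-adjusted Cox model on the combined marker shows the
double-positive effect (hazard ratio with Wald 95% CI; at n = 48 the
interval is wide but clearly excludes 1):

```
             term    coef     hr ci_low ci_high        p
6 `RAR-G1*RAR-G2`  3.0950 22.088  5.784   84.35 5.98e-06
```

For a replication-style cohort, `simulate_qpcr()` produces triplicate
Ct tables, `ddct_calls()` converts them to dosage ratios and gain
calls, and `run_replication()` runs the same survival battery on them.

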