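---
title: "Methods: pan-cancer splicing screens on planted-truth cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer splicing screens on planted-truth cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

## The analysis model

`splicescreen` implements a pan-cancer screen for tumor-associated
cassette-exon (and other alternative-splicing) events in cancer driver
genes, the identification of candidate regulating splicing factors, and a
rule-based patient stratification feeding a survival comparison. The unit
of measurement is the percent-spliced-in value Ψ ∈ [0, 1] of a splice
event in one sample; the unit of inference is the tumor-versus-normal
difference ΔΨ, either of group means (per cancer type) or within a
dually-sampled patient.

The screen makes few distributional assumptions. Group ΔΨ is tested with
a pooled-variance two-tailed Student's *t* — adequate for the n ≥ 10
per-group floor the quantification filter enforces, and chosen over Welch
because the classical test is what desk analyses of PSI tables
conventionally report. Factor association is the Pearson correlation of Ψ
against log2(FPKM + 1); survival uses the nonparametric product-limit
estimator and log-rank test. Everything downstream of the raw tables is a
deterministic function of (data, thresholds, seed).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `top_n` | 60 | genes per cancer type in the mutation-frequency ranking |
| `min_n` | 10 | non-missing samples per tissue group for "quantified" |
| `quantified_frac` | 0.80 | minimum fraction of types quantified (inclusive) |
| `min_detected` | 12 | minimum types detected (p < `alpha` or \|ΔΨ\| > floor) |
| `alpha`, `dpsi_floor` | 0.05, 0.01 | detection rule components |
| `paired_threshold` | 0.15 | per-patient \|ΔΨ\| alteration cut, strict `>` |
| `low_pct` | 12 | percentile below which non-mutant expression leaves WT |
| `marker_cut` | 1.75 | strict normalized-FPKM marker-high cut |
| `split_rule` | median | high/low expression split (ties to high) |

"Quantified" and "detected" are deliberately distinct: quantification is
a per-group sample-size floor (it decides whether ΔΨ is estimable at
all), while detection additionally asks for evidence of change. Both
appear in the cross-cancer filters — an event must be quantified in
≥ 80 % of types *and* detected in ≥ 12 — because a pan-cancer ranking on
sparsely quantified events would reward missingness. The pan-cancer score
is the mean of |ΔΨ| over quantified types only; zero-imputing
unquantified types would penalize such events twice.

Counting "most frequently mutated" as *distinct non-silent mutated
patients* (not mutation records) reflects how cohort mutation frequencies
are conventionally reported; silent variants neither count here nor
confer Mut status in stratification. The driver set is the union of
per-type top-`top_n` lists intersected with the catalogue — the only
composition that yields a single pooled driver list — with ties broken by
gene symbol and a hard cut at `top_n`, so the result is deterministic and
row-order independent.

Threshold semantics follow their verbal definitions exactly: the paired
alteration rule is strict (a patient at ΔΨ = 0.15 exactly is *not*
altered), as is the marker-high cut at 1.75. The "below 12 %" low-expression
rule is read as the 12th percentile of the target gene's tumor expression
among non-mutant patients, computed per cancer type; it is the only
percentile reading that produces a "low-FPKM" class disjoint from Mut.
Mut takes precedence over LowExpr.

## The synthetic cohort generator

`generate_bundles(sim_config())` emits linked tables for 15 cancer types
(60 tumor / 30 normal samples each, 15 patients dually sampled) with:

* ~36 driver genes × 3 exon-skipping events whose baseline Ψ per event is
  Beta-distributed (mean uniform on [0.1, 0.9], concentration 30);
* one planted event (baseline mean 0.75) shifted by ΔΨ = −0.2 in tumor
  samples of 12 of the 15 types;
* one regulator among 172 splicing factors whose standardized tumor
  log-expression couples to the planted event's tumor Ψ through
  Ψ = clamp(μ + δ + b·z + ε), ε ~ N(0, 0.08), with b solved from
  r = b/√(b² + σ²) so the target correlation (−0.6) is attained in
  expectation; the coupling standardizes the *realized* expression within
  each type, so the planted tumor-side expression shift (+0.8 log2 units
  in planted types) moves Δexpression without moving ΔΨ;
* per-gene Bernoulli mutations (target gene at rate 0.4, the approximate
  clear-cell renal-cell fraction; others uniform in [0.02, 0.3]);
* a marker gene whose tumor FPKM gains `marker_effect`·Ψ only in patients
  without a non-silent target-gene mutation (baseline ≈ 0.8 ± 0.25), so
  the marker/Ψ association exists in the WT stratum and vanishes under
  mutation;
* exponential survival at baseline hazard log 2 / 800 per day with the
  hazard multiplied by 2.5 for patients who are simultaneously target-gene
  WT, regulator-low (median split) and in the first treatment arm, and
  uniform censoring whose window is solved to give ≈ 30 % censoring.

Two planted quantities could conflict: the *group-level* tumor shift
(ΔΨ = −0.2) and the *per-patient* altered fraction (0.5 of pairs beyond
the 0.15 cut). A naive per-patient bimodal shift would inflate tumor-Ψ
variance and dilute the regulator correlation well below its target. The
generator therefore gives unpaired tumor samples the full group shift,
while dually-sampled patients receive a constant shift *m* calibrated so
that P(|paired ΔΨ| > 0.15) equals the altered fraction exactly, given the
closed-form noise SD √(b² + 2σ²) of a paired difference. This keeps the
paired-alteration count exactly Binomial(n_paired, fraction), adds no
variance component to tumor Ψ, and biases the per-type group ΔΨ by less
than 0.015 at the defaults — within the generator's ±0.02 calibration
property. With a zero planted shift no paired shift is applied, so null
configurations stay null.

Randomness streams from the single config seed with fixed per-type
offsets, so adding a cancer type does not reshuffle the others, and
identical seeds give byte-identical TSV output (PSI is serialized at the
4-decimal precision of the emulated source tables).

What the generator does **not** emulate: correlated gene networks,
read-level sampling noise in Ψ, batch effects, copy-number interactions,
non-exponential hazards, or informative censoring. Passing recovery tests
on these cohorts therefore demonstrates the pipeline's correctness and
operating characteristics under its own stated model, not performance on
real TCGA data.

## Numerical choices and degenerate inputs

* Ties: expression splits send values at the median to "high"; ranking
  ties break by symbol/event id; log-rank processes events before
  censorings tied at the same time.
* Ψ outside [0, 1], negative FPKM, non-positive survival times and
  unknown tissue labels are validation errors naming the offending cell;
  unknown MAF variant classes map to `other` with a warning rather than
  failing a whole table.
* Correlations below 10 complete pairs, or with a constant series, are
  reported as unevaluated with a reason, never as 0.
* |r| = 1 is reported with p = 0 (the *t* transform diverges).
* Dunnett's many-to-one adjustment is estimated by seeded Monte-Carlo
  simulation of the max-|t| null (default 2·10⁵ draws) and reported with
  its Monte-Carlo standard error; the suite checks it against the
  multivariate-*t* computation in `multcomp` within that error. This
  trades a dependency on quadrature internals for an estimator whose
  accuracy is visible in its output.
* A singular log-rank variance (e.g. no events at all) yields χ² = 0
  rather than an error: no events is no evidence against the null.

## Validation design and problem sizes

The suite validates each primitive against an independent oracle on fixed
fixtures (hand arithmetic, `t.test`, `cor.test`, `aov`, `p.adjust`,
`survival::survfit`/`survdiff`, exhaustive set-counting for mutation
frequencies, brute-force O−E tabulation for the log-rank), and validates
the screens against the generator's ground truth: planted-event rank-1
recovery in ≥ 95 % of 20 cohorts at the default conditions, regulator
rank-1 recovery in ≥ 90 % with the realized correlation within ±0.15 of
its target, binomial-interval coverage of the paired-alteration estimate
in ≥ 90 % of 50 cohorts, log-rank size 5 % ± 2 % over 1000 null
replicates of 120 patients, and power ≥ 80 % over 50 replicates with
≈ 120 patients in the analyzed arm at the planted hazard ratio 2.5 (the
null-arm rejection staying at chance). Monte-Carlo replicate counts are
the package's chosen operating points for these checks; the same
quantities are recomputed by `scripts/acceptance.R`.

## Known limitations

* Only the four standard event classes (ES, AA, AD, RI) are modeled;
  mutually-exclusive-exon and complex events are out of scope, as is
  recomputing Ψ from reads or junction counts.
* The expression split rules (median/tertile/threshold) are pragmatic
  defaults; the cut behind a published "high vs low" split is often
  unstated, so every report records the rule used.
* The marker-high flag operates on whatever normalized expression matrix
  is supplied; it does not itself normalize.
* No multiple-testing correction is applied inside the factor screen by
  default (raw r/p are reported, matching screening practice); a
  Benjamini–Hochberg column is available via `bh = TRUE`.
* Survival analysis is limited to Kaplan–Meier and log-rank;
  proportional-hazards modeling and covariate adjustment are out of
  scope.
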