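# splicescreen

`splicescreen` is a tidyverse-native R toolkit for pan-cancer
alternative-splicing screens of the kind used to nominate exon-skipping
events in cancer driver genes and the splicing factors that regulate them,
and to connect the resulting splice isoforms to patient outcome under
immune-checkpoint therapy.

It is aimed at computational biologists working with SpliceSeq-style
percent-spliced-in (PSI) tables, FPKM expression matrices, MAF-style
somatic mutation calls and clinical survival records — and at anyone who
wants to validate such a screen end to end on synthetic cohorts with known
planted structure before pointing it at real data.

## What it computes

For a cassette exon, Ψ (PSI) is the fraction of a gene's transcripts that
include the exon, in [0, 1]. The pipeline's stages are:

1. **Driver compilation** — rank genes per cancer type by the number of
   distinct patients with a non-silent somatic mutation, take the top *n*
   (default 60), and intersect the union of the per-type lists with a
   curated driver catalogue.
2. **Event screen** — per (event, cancer type), ΔΨ = mean Ψ(tumor) − mean
   Ψ(normal) with a pooled two-tailed Student's *t*; events quantified in
   ≥ 80 % of types and detected in ≥ 12 of 15 are ranked by the mean of
   |ΔΨ| over quantified types.
3. **Paired alterations** — per dually-sampled patient,
   ΔΨ = Ψ(tumor) − Ψ(normal); a patient is *altered* when |ΔΨ| > 0.15
   (strict), and the alteration frequency is the altered fraction of
   evaluable pairs.
4. **Factor screen** — Pearson correlation of event Ψ against
   log2(FPKM + 1) of each of 172 splicing factors within each cancer
   type's tumor samples; factors ranked by the median *r* across types.
   A cross-cancer correlation of per-type ΔΨ against per-type Δexpression
   complements the within-type screen.
5. **Stratification and survival** — patients classed WT / Mut / LowExpr
   for the target gene (LowExpr = non-mutant below the 12th expression
   percentile), split high/low on regulator expression, flagged on a
   marker (e.g. PD-L1 > 1.75 normalized FPKM, strict), and compared by
   the Kaplan–Meier product-limit estimator with the log-rank test.

All statistics (two-sample *t*, Pearson *r*/*p*, one-way ANOVA with
Bonferroni or Monte-Carlo Dunnett adjustment, Kaplan–Meier, log-rank) are
implemented in the package and cross-checked in the test suite against
independent oracles (`t.test`, `cor.test`, `aov`, `survival::survfit`,
`survival::survdiff`, `multcomp`). Bench-side calculators (molar gel-band
proportions, restriction-digest variant ratios, ellipsoid tumour volume
V = π/6 · L · W², % specific lysis) are included as pure functions.

The synthetic-cohort generator (`sim_config()` + `generate_bundles()`)
plants a differentially spliced event (ΔΨ = −0.2 in 12 of 15 types), an
anti-correlated regulator (*r* = −0.6) among the factors, a marker gene
coupled to event Ψ only in target-gene wild-type patients, and an
exponential survival model with hazard ratio 2.5 for the susceptible
stratum — so every stage has a ground-truth recovery target.

## Worked example

```r
library(splicescreen)

cfg <- sim_config(seed = 1)          # the default study conditions
report <- run_screen_pipeline(cfg, arm = "nivolumab")
report
#> <screen_report>
#>   drivers: 36 genes; events ranked: 10
#>   top event: PBRM1|ES|27|25|28 (mean |dPSI| = 0.146)
#>   paired alteration frequency: 0.418 (89/213)
#>   top factor: RBFOX2 (median r = -0.612)
#>   log-rank (C01, nivolumab): chi2 = 3.666, p = 0.0555
```

The planted event tops the ranking with a pan-cancer mean |ΔΨ| of 0.146
(the planted −0.2 shift averaged over the 12 carrying types and diluted by
the three null types); 41.8 % of evaluable tumor/normal pairs exceed the
0.15 paired-alteration cut (0.5 was planted within the 12 carrying types,
pooled here across all 15); and the planted regulator is recovered at
rank 1 with a median per-type correlation of −0.612 against its −0.6
target. The log-rank comparison of the high-E27 functional stratum
(target-gene WT ∧ regulator-low) against everyone else in one ~30-patient
treatment arm is underpowered by design at this cohort size — the
acceptance script below measures power at the intended n.

```r
head(as.data.frame(report$event_ranks), 3)
#>            event_id  gene mean_abs_dpsi n_types_quantified rank
#> 1 PBRM1|ES|27|25|28 PBRM1    0.14630375                 15    1
#> 2 PBRM1|ES|33|32|34 PBRM1    0.02456008                 15    2
#> 3 DRV14|ES|13|12|14 DRV14    0.02233050                 15    3

ggplot2::autoplot(report$event_ranks)               # delta-PSI heatmap
ggplot2::autoplot(report$factor_ranks, highlight = "RBFOX2")
```

Individual stages are plain functions over tibbles and compose with the
pipe: `read_psi_table()` / `read_expr_table()` / `read_mutations()` /
`read_clinical()` ingest the TSV dialects, `summarize_events()` |>
`filter_events()` |> `rank_events()` is the event screen, and so on.

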