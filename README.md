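# urostab

Temporal stability analysis of the human urinary microbiota from paired
urine samples.

## The problem

Microbiome–disease associations are only clinically useful if a subject's
microbiota profile means something beyond the day it was sampled.  For the
urinary tract this is largely unquantified: how many of the OTUs
(operational taxonomic units — 16S rRNA clusters at 97% similarity) found in
a urine sample are still present months or years later, and how much of the
community do those persistent taxa represent?

`urostab` implements the full statistical pipeline for paired-design
cohorts in which every subject contributes two samples separated by a known
interval:

* **I/O and validation** — dense-TSV and sparse-triplet OTU tables, sample
  and subject metadata, with a column-mapping configuration for externally
  deposited tables.
* **Quality control** — Good's coverage gate (`C = 100(1 - F1/N)`, pairs
  excluded when either sample is below 85%), global-singleton removal,
  relative-abundance normalization.
* **Alpha diversity** — iterated rarefaction (default 1,000 reads × 1,000
  iterations) with bias-corrected Chao1 `S_obs + F1(F1-1)/(2(F2+1))` and
  Shannon entropy `-Σ p_i log p_i`.
* **Overlap statistics** — per subject, the OTUs detected at both
  timepoints and their **shared relative abundance**
  `(abundance_1 + abundance_2)/2`, plus sex-stratified prevalence tables
  and a dominant-discordant diagnostic.
* **Beta diversity** — Bray–Curtis dissimilarity `Σ|x−y|/Σ(x+y)` with a
  permutation PERMANOVA (Gower centering, sequential sums of squares,
  per-term R², exact enumeration on small designs, optional restricted
  permutations).
* **Temporal decay model** — `shared_pct ~ months + age + sex + cancer
  [+ method]` by OLS with Wald-t intervals, marginal R² and standardized
  betas, plus an interval-split subgroup analysis and the standard paired /
  group tests (Wilcoxon signed-rank, rank-sum, Kruskal–Wallis, t).
* **Synthetic cohorts** — a generator with known persistence and drift
  (mixture weight `w = clamp((intercept + slope·months + ε)/100, 0, 1)`
  carried by a persistent taxon subset at both timepoints), so every stage
  is testable by parameter recovery with no external data.

See the methods vignette
(`vignettes/urinary-microbiota-stability.Rmd`) for the model details and
design rationale.

## Worked example

Simulate a cohort at the default configuration (63 subjects, intervals
3–40 months, drift −0.66 %/month with ±15% noise) and run the core
analysis:

```r
library(urostab)

g  <- generate_cohort(synthetic_config(), seed = 42)
qc <- qc_cohort(g$cohort)              # coverage gate + singleton removal
ov <- cohort_overlap(qc$cohort)        # per-subject persistence statistics
ov
#> Overlap summary for 63 subjects
#>   OTUs per sample:      87 +/- 55
#>   overlapping OTUs:     34 +/- 25 (46% +/- 28%)
#>   shared rel. abund.:   81.8% +/- 16.5% (median 85.4%)

fit <- decay_model(ov)                 # shared_pct ~ months + age + sex + cancer
fit
#> Shared-abundance decay model (OLS), n = 63 subjects
#> response: shared_abund_mean (% scale); marginal R2 = 0.25
#>         term estimate          95% CI      t df        p
#>  (Intercept)  105.000 [85.18, 125.29] 10.500 58 4.86e-15
#>       months   -0.636  [-0.99, -0.28] -3.600 58 6.68e-04
#>          age   -0.206   [-0.47, 0.05] -1.580 58 1.19e-01
#>         sexM    5.110  [-2.70, 12.93]  1.310 58 1.95e-01
#>       cancer    1.670   [-5.90, 9.24]  0.442 58 6.60e-01
```

Reading the output: each pair of urine samples from this simulated subject
pool shares on average 34 OTUs, but those persistent taxa carry 81.8% of
the community's relative abundance, and that shared fraction declines by an
estimated 0.64 percentage points (95% CI 0.28–0.99) for every additional
month between collections; age, sex and cancer status show no significant
effect.  `interval_subgroup_analysis(ov)` contrasts short- against
long-interval subjects, and `permanova(distance_matrix(...), ...)`
partitions Bray–Curtis variance among design factors.

The one-shot driver `run_pipeline(pipeline_config(simulate = list(), seed
= 1), out_dir = "out")` executes qc → alpha → overlap → beta → models and
writes per-stage TSVs, a JSON summary of the headline aggregates and a run
log; `inst/scripts/urostab.R` wraps it for shell use.  Real data enter via
`read_otu_table()` + `read_metadata()` + `build_paired_cohort()`.

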