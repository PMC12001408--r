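---
title: "Methods: quantifying temporal stability of the urinary microbiota from paired samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying temporal stability of the urinary microbiota from paired samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urostab)
```

## The question and the data model

How much of an individual's urinary microbiota is still there when a second
urine sample is collected months or years after the first?  `urostab`
answers this for paired-design cohorts: each subject contributes exactly two
samples (timepoints 1 and 2, separated by a known interval in months), the
community in each sample is summarized as a vector of OTU counts
(operational taxonomic units, 16S rRNA clusters at 97% similarity), and
subject-level covariates (sex, age, cancer status, urinary stones,
collection method) are available.  The first collection may be mid-stream
voided urine (MSU) or catheterized urine; the second is MSU by design, and
the package warns rather than fails when external data violate that
expectation.

Everything downstream operates on a `paired_cohort`: a validated bundle of
an integer `samples x OTUs` matrix and the two metadata tables.  Ids are
kept in canonical (C-collation lexicographic) order internally, which makes
every statistic invariant to the row order of the input files.

## Quality gating and normalization

The pipeline order is fixed: **coverage gate, then global-singleton removal,
then normalization**.

* **Good's coverage** per sample is `100 * (1 - F1/N)` percent, with `F1`
  the number of OTUs seen exactly once in that sample and `N` its reads.  A
  subject is excluded — both samples — when either sample falls strictly
  below the threshold (default 85%).  Coverage is computed on raw counts,
  before any OTU filtering, so the gate decision can never depend on later
  filtering choices.
* **Global singletons** — OTUs whose summed count across the whole dataset
  is exactly 1 — are removed afterwards as likely artifacts.  Per-sample
  singletons (used by the coverage estimator) and global singletons are
  deliberately distinct concepts with distinct names.
* **Relative abundances** are proportions in `[0, 1]` internally; only
  reporting layers multiply by 100.  A zero-read sample is an error at this
  stage, never silently dropped.

## Alpha diversity under iterated rarefaction

Unequal sequencing depth is standardized by subsampling each sample without
replacement (multivariate hypergeometric) to a fixed depth (default 1,000
reads), excluding any subject with at least one sample below that depth.
Subsampling is repeated (default 1,000 iterations) and per-sample means and
SDs of the indices are reported:

* **Chao1**, bias-corrected: `S_obs + F1(F1-1) / (2(F2+1))`.  The
  bias-corrected form is the default because it stays finite when no
  doubletons exist; the classic `S_obs + F1^2/(2 F2)` variant is available
  for sensitivity runs.
* **Shannon** entropy `-sum p_i log p_i` in nats by default (the base is an
  argument).

Each sample draws from its own RNG stream seeded by `(seed, sample_id)`, so
results are bit-reproducible and independent of cohort ordering.  The
rarefaction machinery is validated against the closed-form expected rarefied
richness `sum_i (1 - C(N - n_i, d)/C(N, d))`.

## Overlap statistics: the persistence measure

For each subject the package counts OTUs detected (count > 0) at both
timepoints and computes the **shared relative abundance**: the summed
relative abundance of those overlapping OTUs in each sample, and the average
of the two, `(abundance_1 + abundance_2)/2`.  This average is the central
stability statistic — it asks not just *how many* taxa persist but *how much
of the community* they represent.

The overlap *fraction* needs a denominator and none is canonical; the
default is the mean of the two per-sample richness values, with `union` and
`min` available as alternatives (the choice is reported alongside results).
Presence means any nonzero count after singleton removal — no extra
detection threshold is imposed.  Two companion outputs: a prevalence table
of OTUs detected in both samples of a subject, tallied by sex with a
configurable prevalence cut (default 50% in either sex); and a
dominant-discordant diagnostic flagging OTUs above 50% relative abundance in
one sample of a pair but absent in the other, the signature of a flipped
community.

## Beta diversity: Bray-Curtis PERMANOVA

Between-sample dissimilarity is Bray-Curtis,
`sum|x_i - y_i| / sum(x_i + y_i)`.  Variance partitioning uses the
McArdle-Anderson construction: squared dissimilarities are Gower-centered
into an inner-product matrix, each term's sequential (Type-I) sum of squares
is the trace of that matrix projected onto the term's design columns, and
`pseudo-F = (SS_term/df_term)/(SS_res/df_res)`.  Significance comes from
permuting sample labels; `R^2 = SS_term/SS_total`.

Numerical and inferential choices:

* The p-value uses the add-one estimator `(1 + #{F* >= F})/(1 + B)`, so it
  is never exactly zero.  With `permutations = "exact"` all label
  permutations are enumerated (supported to n = 8) and the p-value is the
  exact tie-inclusive proportion.
* A permuted statistic within floating-point jitter of the observed one
  counts as a tie; without this floor, genuinely tied permutations would be
  missed at random.
* Because single-variable effects are the reporting unit for this design
  (subject identity, interval, sex, cancer, collection method), the pipeline
  fits one term at a time by default; a sequential multi-term mode exists
  and logs its term order, since Type-I sums of squares are order-dependent.
* Permutations are free by default.  A `strata` argument restricts
  permutation within groups (e.g. within subject for paired layouts); which
  scheme a given study used is rarely stated, so both are exposed.
* Residual sums of squares are floored at zero: Gower centering can produce
  `-1e-17` in clean separable toys, which would otherwise flip the sign
  of an effectively infinite F.

## The temporal decay model

The decline of shared relative abundance with collection interval is
modelled on the percent scale:

```
shared_pct ~ months + age + sex + cancer [+ method]
```

with sex coded F = 0 and cancer 0/1, so the intercept is the expected shared
abundance at a zero interval for a cancer-free female of age zero.  A
subject-level random intercept is the natural impulse for repeated-measures
data, but with exactly one response row per subject it is unidentifiable —
completely confounded with the residual — and any mixed-effects fit
degenerates to the same fixed-effect estimates.  `decay_model()` therefore
uses ordinary least squares with Wald-t confidence intervals as its primary
profile, and offers a REML profile (via nlme) for genuinely replicated
designs; on one-row-per-subject data the two coincide in their fixed
effects, which the test suite asserts.

Reported alongside the coefficients: marginal R² (variance of fixed-effect
predictions over variance of the response — for OLS this is the ordinary
R²), and standardized betas obtained by z-scoring the *continuous
predictors only* (the response is untouched; the convention is flagged in
the output because both conventions circulate).

Supporting analyses: squared Pearson correlation between overlap counts and
shared abundance; Wilcoxon signed-rank for paired alpha-diversity contrasts
(zeros dropped, exact sign-enumeration null up to 25 untied pairs, tie- and
continuity-corrected normal approximation beyond); rank-sum,
Kruskal-Wallis and Student/Welch t for group contrasts.  Test choice is an
explicit argument — there is no hidden normality-based auto-switch, which
would make analyses irreproducible across cohorts.  A subgroup analysis
splits subjects at 15 months (configurable) and reports group means, SDs
and within-group interval-only slopes.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage — and especially the decay
estimator — can be validated by parameter recovery without any external
download.  Defaults emulate the motivating study population: 63 subjects,
intervals uniform on 3–40 months, sequencing depth log-normal with mean
11,524 and SD 8,669 reads truncated at 1,000, per-subject taxon pools
log-normal with mean 152 and SD 128 OTUs (truncated to `[5, pool/2]` so the
2,000-OTU global pool can always supply novel taxa), long-tailed Dirichlet
compositions (concentration 0.3), 43/63 male, 28/63 with bladder cancer,
22/63 with stones, 26/63 catheterized first samples, age normal (61.1,
14.8) truncated at 18.

The drift mechanism is deliberately modelled **on the shared-abundance scale
itself**, not through per-taxon dynamics: each subject receives a persistent
subset of their taxon pool (Bernoulli, probability 0.27 per taxon), and the
persistent component carries mixture weight

```
w = clamp((99.78 - 0.66 * months + e) / 100, 0, 1),   e ~ N(0, 15)
```

of the community at *both* timepoints, with the remaining `1 - w` spread
over transient taxa at timepoint 1 and novel taxa at timepoint 2.  Reading
`w` as the fraction of community mass that persists across the interval
makes it a symmetric quantity: the shared abundance measured at either
timepoint then equals `w` up to multinomial detection loss, which is what
makes the configured slope identifiable by the pipeline's own estimator.
(Applying drift at timepoint 2 only would halve the recoverable slope, since
the response averages both timepoints.)

Two honest consequences of this design, both quantified by the recovery
simulation in the acceptance suite:

* **Censoring attenuation.**  With an intercept near 100% and 15% noise,
  the clamp at 100% fires frequently at short intervals.  `E[w | months]`
  is therefore concave rather than linear, and a straight-line fit to the
  censored response recovers a slope biased toward zero relative to the
  configured coefficient — an intrinsic property of a bounded response
  generated near its ceiling, not an estimator defect.  The generator
  reports how often the clamp fired; the recovery simulation measures the
  resulting bias.
* **Detection loss.**  Low-weight persistent taxa can be missed by the
  multinomial draw at finite depth, slightly deflating the measured shared
  abundance; at high depth the per-subject measurement converges on `w`,
  which the tests assert directly.

What the generator does *not* emulate: phylogenetic structure among taxa,
taxon-level ecological dynamics, compositional correlations between the two
timepoints beyond the persistent/transient split, PCR and chimera artifacts,
or the empirical (unknown) distributional forms of richness and depth — the
log-normal choices are pragmatic defaults, all overridable.  Passing
recovery tests therefore demonstrates that the pipeline measures what it
claims on communities whose drift really is linear-with-censoring; it does
not certify the linear model as the true generative law of real urinary
communities.

## Problem sizes used by the test suite

The package's own validation uses: hand-computable fixtures of 2–6 samples;
brute-force oracle sweeps of 100 random instances per statistic;
hypergeometric rarefaction checks at 1,000 iterations on 20 random samples;
exact PERMANOVA enumeration on six-sample toys plus a 500-replicate null
calibration; exact rank-test enumeration up to 20 observations; and the
recovery study of 200 cohorts of 63 subjects at the default generator
configuration, which is also what `scripts/acceptance.R` re-runs.

## Known limitations

* The decay model is linear in the interval; saturating or non-monotone
  drift is out of scope, and the bounded response means the linear
  coefficient should be read as an average rate over the observed interval
  range.
* PERMANOVA assumes exchangeability of samples under the null; with paired
  samples the free-permutation default is anticonservative for
  within-subject terms, which is why `strata` exists.
* The prevalence table reports raw per-sex percentages with no multiplicity
  adjustment, matching descriptive practice for such tables.
* BIOM is supported in its plain-text triplet form only; HDF5 containers
  must be exported to TSV first.
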