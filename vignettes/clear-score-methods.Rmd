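---
title: "Continuous aggressiveness scoring of ccRCC expression profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous aggressiveness scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearscore)
```

## Motivation and model

Unsupervised subtyping of clear cell renal cell carcinoma (ccRCC)
expression data produces unstable, parameter-dependent cluster counts,
while the clinical correlates of aggressiveness — nuclear grade, stage,
tumor size — vary continuously. This package therefore scores each sample
*continuously* by where it falls between two reference expression states
rather than assigning it to a discrete class.

Given a log-scale genes × samples matrix:

1. **Gene filter.** Keep genes with log expression > `gene_filter_threshold`
   (default 8) in at least `gene_filter_fraction` (default 10%) of samples,
   i.e. `ceiling(fraction * n)` samples. This is the published training
   filter. (The source publication states both "792 genes" and "N = 7924"
   for its own cohort — mutually inconsistent as printed; this
   implementation simply uses whatever the filter yields and takes no side.)
2. **Reference sample sets (RSSs).** Samples at the two clinical extremes
   of an axis: grade 1 vs grade 4 by default; lowest vs highest observed
   stage; bottom vs top size quartile (the extremes for a continuous axis
   were never specified upstream — quartiles are this package's choice,
   configurable via `quantile_cut`). Per-gene centroids are medians by
   default (`centroid_statistic`): the upstream description says both
   "average" and "median" in one sentence, and the median is the robust
   reading.
3. **Raw score.** For sample S and `n_boot` (default 100) random subsets of
   `subset_fraction` (default 0.5) of the filtered genes,
   `CS = mean_i d(S, low, g_i) / d(S, high, g_i)` with
   `d = 1 − cor(…)` (Pearson by default). Neither the subset count nor the
   subset size is anchored upstream; both defaults are documented
   conventions and configurable.
4. **Scaling.** `S = (CS − min P)/(max P − min P) * 99 + 1`, fitted on the
   scoring cohort, so the cohort spans exactly [1, 100]. New samples are
   projected with the frozen bounds and clamped.

### The distance convention

The upstream equations literally set "Dist = Corr" yet call it a
*correlation distance*, and associate high scores with high grade. Taken
literally (ratio of correlations), a sample resembling the grade-1 centroid
would score *high* — contradicting that association. The default here is
`distance_kind = "one_minus_corr"` (d = 1 − r), which makes high scores
grade-4-like and reproduces the published direction; the literal
`"raw_corr"` reading is retained as a config option for fidelity
experiments. Which one the original code used is undecidable from the text;
this package does not claim to know.

### Numerical conventions

* Distances are floored at `epsilon` (1e−8) before the ratio, so a sample
  identical to a centroid on a subset yields a finite ratio instead of a
  dropped draw.
* A subset on which correlation is undefined (zero variance) is redrawn;
  more than 50% redraws aborts.
* Per-sample RNG seeds are `seed + hash(sample_id) mod (2^31 − 1)`, so a
  sample's score is invariant to cohort order and subsetting. All
  randomness is Mersenne-Twister.
* Degenerate scaling (all raw scores equal) maps every sample to the
  midpoint 50.5 with a warning rather than dividing by zero.
* Tied scores at an even-grouping boundary are resolved by sample id and
  logged.

## Signature derivation

Three ranking queues order the cohort by grade-, stage- and size-anchored
scores. Each gene is rank-correlated (Spearman and Kendall) with each
queue position; the per-(gene, queue) screen statistic is the mean of the
two coefficients — how the two screens combine was unstated upstream, and
averaging is this package's choice (requiring sign agreement is possible
via the per-gene table). Per queue, the `top_k_each_tail` (default 100)
most positive and most negative genes are kept; the upstream phrase "three
most positively and negatively correlated gene sets" is ambiguous and is
read as one positive and one negative set per queue. "Common" genes are the
set intersection across queues, ranked by mean |screen| and truncated to
`n_common = 50`; an empty intersection falls back to the union with a
warning. Finally a univariate Cox proportional-hazards score test per
candidate (the unstated "sensitivity analysis" is reconstructed this way)
ranks genes by p-value; the `n_select = 18` smallest form the signature.
No multiple-testing correction is applied — this is selection, not
inference — and the published 18 gene identities are not reproduced or
hard-coded: the signature is data-derived.

## Survival validation and model comparison

Kaplan-Meier curves, the k-group log-rank test and Cox fits are delegated
to the `survival` package with the Efron tie convention (unspecified
upstream; configurable). Even grouping along the scale sorts by score and
splits into blocks whose sizes differ by at most one, earlier blocks taking
the extra sample.

`compare_models()` fits null, A, B and A+B proportional-hazards models.
The LR statistic for adding A to B is `2(ll_full − ll_B)` with df =
params(A). The **adequacy index** of a subset model is
`(ll_subset − ll_null)/(ll_full − ll_null)` — the fraction of the full
model's prognostic information the subset captures (Harrell's
log-likelihood formulation). Pseudo-R² is the Cox–Snell form
`1 − exp((2/n)(ll_null − ll_model))`; the upstream text does not state
which variant produced its printed values, so this package reports its
convention rather than claiming equality. Nested log-likelihood
monotonicity is checked on every comparison; an epsilon-level violation
triggers a tighter refit and a genuine violation aborts.

The two-group score comparisons (mutation status, treatment response,
sarcomatoid histology) use a Mann-Whitney U test implemented in-package:
exact permutation enumeration when `choose(n, n1)` ≤ 20 000 (this is what
small-sample claims should rest on), otherwise the normal approximation
with tie and continuity corrections.

## Heterogeneity

* **Stability under reference resampling** (`rss_stability`): bootstrap the
  membership of each extreme group (with replacement — the natural reading
  of "bootstrapping samples"; combinations are kept unique by rejection up
  to a retry cap), rebuild centroids, rescore, and summarise each sample's
  raw-score spread across replicates by the MAD. The published procedure
  used 500 replicates; tests use fewer and verify self-consistency instead.
* **Multi-region heterogeneity** (`multiregion_heterogeneity`): per-tumor
  median score and MAD across regions, pooled MAD over all regions, and
  the Pearson correlation between per-tumor median and MAD. The published
  inter- vs intratumoral comparison cites an ANOVA without stating its
  design; it is reconstructed here as a one-way ANOVA on absolute
  deviations from each region's own tumor median versus deviations from
  the pooled median, with a label-permutation test reported alongside.
  Region scores should be produced with `score_new_samples()` against one
  fitted cohort (frozen centroids and scaling) so scores are comparable
  across tumors.
* **MAD convention:** raw `median(|x − median(x)|)`, no 1.4826 consistency
  factor — the MAD is used descriptively, not as a σ estimate. The factor
  is available via the `constant` argument.

## The synthetic world

`generate_cohort()` encodes the hypothesis the score is built on: each
sample is a convex mixture of two archetypal expression states. Latent
aggressiveness u ~ Uniform[0, 1]; archetypes share a Normal(9, 1)
background and differ by **2 log-units** on `n_informative` (default 30 of
1000) genes; expression = (1−u)·A_low + u·A_high + Normal(0, `noise_sd` = 1).
Grade is `1 + floor(4u)` (capped), stage and size are monotone noisy
transforms of u, and survival is exponential with
log-hazard = 0.003·exp(`hazard_coef`·100u) (baseline 0.003/month,
`hazard_coef` = 0.03 per unit of the 0–100 latent scale) under independent
exponential censoring (`censor_rate` = 0.005/month). The background level 9
against the filter threshold 8 makes the default filter non-trivially drop
some genes. `generate_multiregion()` nests region latents
(Normal(0, `intra_sd`)) around tumor centers (Normal(0.5, `inter_sd`),
truncated), defaults 0.05 and 0.15 (a 3:1 ratio), and by default draws
region counts in 4..9 summing to 65 across 10 tumors, mirroring the
multi-region dataset structure the heterogeneity analysis targets. Passing
one cohort's `archetypes` to a second generation puts both on the same
disease axis — required when projecting regions onto a score fitted
elsewhere, exactly as a fitted clinical score is applied across cohorts.

What the generator does **not** emulate: platform/probe effects, batch
structure, RNA-seq count noise, non-monotone grade–expression
relationships, and correlated gene-gene noise. A green parameter-recovery
test therefore establishes that the pipeline recovers a *planted linear
continuum under independent Gaussian noise* — not that it would perform
equally on any real cohort.

## Design choices on genuinely open points

* Expression is assumed log-scale and pre-normalized (upstream used RMA);
  the loader never normalizes and warns if >1% of values exceed 30.
* Missing expression cells are rejected by default; per-gene median
  imputation is opt-in.
* Whether the original scaling was refit per external dataset or frozen is
  unstated; this package fits on the scoring cohort and freezes bounds for
  projection, with clamping.
* The acceptance contract for this package defines no numeric targets —
  the published headline numbers require external patient cohorts — so
  acceptance is property-based (exact oracle equivalence, reciprocal
  symmetry, bound attainment, parameter recovery, planted-gene recovery,
  adequacy ordering, inter>intra heterogeneity direction, procedural
  constants, exact Mann-Whitney agreement); see
  `tests/testthat/test-acceptance.R`.

## Known limitations

Scores are relative to their reference cohort: absolute values are not
comparable across different RSS pairs or cohorts without projection.
The bootstrap subset count/size and several reconstructed procedures
(survival sensitivity analysis, ANOVA design, Spearman/Kendall
combination) are conventions where the upstream description is silent;
all are configurable and flagged above. No competing risks,
time-dependent covariates, or cross-platform probe harmonization.
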