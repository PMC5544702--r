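# clearscore

A continuous, reference-anchored tumor aggressiveness score for clear cell
renal cell carcinoma (ccRCC) expression profiles, with the full supporting
pipeline: signature derivation, survival validation, nested model
comparison, score-stability assessment, intratumoral heterogeneity
quantification, a seeded synthetic-cohort generator, and a command-line
interface. Everything runs on simulated or toy data; no external downloads
are required.

## Who this is for

Computational biologists who want a *continuous* prognostic readout from a
log-scale expression matrix instead of discrete molecular subtypes — ccRCC
subtype calls are notoriously unstable across clustering parameters, while
clinical variables (nuclear grade, stage, size) distribute continuously.
The score places each sample on the continuum between two reference
expression states.

## The statistic

Two **reference sample sets** (RSSs) anchor the scale at clinical extremes:
by default all grade-1 tumors (RSS1, indolent) and all grade-4 tumors
(RSS2, aggressive). After filtering to genes with log expression > 8 in at
least 10% of samples, per-gene median centroids Expr(RSS1), Expr(RSS2) are
formed. For sample S_k, m bootstrap gene subsets g_1..g_m (half of the
filtered genes each, by default m = 100) give the raw score

    CS_k = (1/m) * Σ_i  d(S_k, RSS1, g_i) / d(S_k, RSS2, g_i)

where d is the correlation distance 1 − Pearson r over the subset (floored
at ε = 1e−8). Cohort scores P = {CS_1..CS_r} are min–max scaled to
[1, 100]:

    S_k = (CS_k − min P) / (max P − min P) * 99 + 1

so 1 = most RSS1-like and 100 = most RSS2-like. Downstream: three clinical
ranking queues (grade/stage/size-anchored scores) are screened against every
gene by Spearman and Kendall rank correlation, the per-queue tails are
intersected (top 50 by default) and a univariate Cox proportional-hazards
sensitivity analysis selects the final signature (18 transcripts by
default). Model value is compared against discrete subtype labels by nested
likelihood-ratio tests and the adequacy index
(ll_subset − ll_null)/(ll_full − ll_null); heterogeneity is quantified by
the median absolute deviation (MAD) of scores across resampled reference
sets and across tumor regions.

## Worked example

```r
library(clearscore)

syn <- generate_cohort(n_samples = 120, n_genes = 300, n_informative = 20,
                       seed = 42)                    # known ground truth
res <- clear_score_pipeline(syn$expr, syn$clin, cfg = clear_config(seed = 42))

df <- data.frame(sample_id = res$sample_ids, grade = res$clin$grade,
                 clear_score = round(res$scaled_scores, 1))
df[order(df$clear_score), ]
#>     sample_id grade clear_score
#> 58       S058     1         1.0
#> 110      S110     1         2.0
#> 35       S035     1         3.5
#> ...
#> 62       S062     4        97.9
#> 2        S002     4        99.8
#> 13       S013     4       100.0

cor(res$raw_scores, syn$latent[res$sample_ids], method = "spearman")
#> 0.932        # the score recovers the latent aggressiveness ordering

g  <- even_groups(setNames(res$scaled_scores, res$sample_ids), 4)
lr <- km_logrank(g, res$clin$time, res$clin$event)
c(chisq = lr$chisq, df = lr$df, p = lr$p)
#> chisq 38.63   df 3   p 2.08e-08   # survival separates along the scale

sig <- derive_signature(syn$expr, syn$clin, clear_config(seed = 42),
                        n_common = 30, n_select = 10)
sum(sig$signature_genes %in% syn$informative_genes)
#> 10           # all 10 signature picks are planted informative genes
```

Low scores are grade-1-like (indolent), high scores grade-4-like
(aggressive); the even score groups Q1–Q4 show increasingly poor
cancer-specific survival, and the derived signature recovers the genes that
actually drive the simulated continuum.

## Command line

```sh
Rscript inst/cli/clear simulate cohort --out-dir sim --seed 7
Rscript inst/cli/clear score --expr sim/expression.tsv --clin sim/clinical.tsv \
        --axis grade --low 1 --high 4 --seed 7 --out scores.tsv
Rscript inst/cli/clear survival --scores scores.tsv --clin sim/clinical.tsv \
        --groups 2,4,6,8 --out km.tsv
Rscript inst/cli/clear derive-signature --expr sim/expression.tsv \
        --clin sim/clinical.tsv --out signature.tsv
```

Subcommands: `score`, `derive-signature`, `survival`, `compare`,
`stability`, `heterogeneity`, `simulate`. Each successful run writes a
`.manifest.json` (resolved config, input digests, seed, version) next to
its output; identical manifests reproduce identical outputs.

## Documentation

`vignettes/clear-score-methods.Rmd` describes the model, every tunable
parameter with its default and rationale, what the synthetic generator does
and does not emulate, numerical conventions, and known limitations.
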