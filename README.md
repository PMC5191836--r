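# diffrhythm

Differential rhythmicity analysis for time-course omics: harmonic
(cosinor) regression with BIC model selection across experimental
conditions, rhythm-parameter extraction, a trend-augmented variant for
metabolite series, glucocorticoid-style *rescue* classification between
untreated and treated study arms, and hypergeometric enrichment
statistics — plus a ground-truth simulator so the whole pipeline can be
exercised and validated without access to any particular dataset.

## Who this is for

Chronobiology and metabolism labs comparing diurnal expression or
metabolite rhythms across genotypes and treatments: e.g. *which genes
lose or shift their daily rhythm in a hormone-deficient mutant, and how
much of that is restored by constant hormone replacement?*

## The model

For a feature measured in condition *c* at Zeitgeber time *t* (hours
after lights-on), on the log2 scale:

    y_c(t) = mu_c + alpha_g(c) * cos(2*pi*t/24) + beta_g(c) * sin(2*pi*t/24) [+ gamma_c * t] + noise

Every candidate model keeps a free mean per condition and chooses, for
each condition, "non-rhythmic" or membership in a rhythm group; groups
share the (alpha, beta) pair. That yields sum_k C(C,k)·Bell(k)
candidates — 5 models for two conditions, 15 for three, 52 for four.
Candidates are fitted by least squares, scored with
`BIC = n ln(RSS/n) + k ln(n)`, and compared through Schwarz weights
`w_j ∝ exp(-ΔBIC_j/2)`; a feature whose best weight misses a
condition-count-dependent threshold is called *ambiguous*. Fitted
harmonics are reported as peak-trough amplitude `2*sqrt(alpha^2+beta^2)`,
peak phase `atan2(beta, alpha)` in ZT hours, and relative amplitude
`(max-min)/mean`. See the methods vignette
(`vignettes/differential-rhythmicity.Rmd`) for the full reasoning behind
each choice.

## Worked example

Simulate a three-genotype cohort at the package's default study design
(ZT 3/9/15/21, two replicates, peak-trough amplitude 2, noise sd 0.1)
and select the best rhythmicity model per feature:

```r
library(diffrhythm)

cfg <- simulation_config(n_features = 200, seed = 42)
sim <- simulate_matrix(cfg)
sel <- select_all(sim$matrix, sim$sheet)
sel
#> rhythm_selection: 200 features, 15 candidate models, 3 conditions
#>   period = 24 h, trend = none, BICW threshold = 0.5
#>   ambiguous: 22, unfittable: 0
head(as.data.frame(sel)[, 1:8], 3)
#>    feature_id                             best_model best_weight ambiguous
#> 1 feature0001 WT=rhythm1|weak=rhythm2|strong=rhythm3   0.9999999     FALSE
#> 2 feature0002          WT=flat|weak=flat|strong=flat   0.5473410     FALSE
#> 3 feature0003    WT=flat|weak=rhythm1|strong=rhythm2   0.9185163     FALSE
#>   fittable threshold_used amplitude.WT phase.WT
#> 1     TRUE            0.5     1.962539 10.80054
#> 2     TRUE            0.5     0.000000       NA
#> 3     TRUE            0.5     0.000000       NA
```

Feature 1 was generated rhythmic in all three genotypes with distinct
parameters and is recovered as such with near-certain confidence; its
wild-type peak-trough amplitude (truth: 2) is estimated at 1.96 log2
units peaking at ZT 10.8. Feature 2 is a flat gene: the flat model wins,
and no phase is reported.

A paired rescue study — untreated wild-type/weak/strong arms plus
treated wild-type/strong arms with 40% of affected features planted as
rescued — is classified back:

```r
study <- simulate_rescue_study(
  config_untreated = simulation_config(n_features = 400, seed = 7),
  rescue_fraction = 0.4, seed = 7)
sel_u <- select_all(study$untreated$matrix, study$untreated$sheet)
sel_t <- select_all(study$treated$matrix, study$treated$sheet)
calls <- classify_rescue(sel_u, sel_t, reference = "WT", mutant = "strong")
rescue_summary(calls)[, c("n_applicable", "frac_rescued_full",
                          "frac_rescued_partial", "rescued_fraction")]
#>   n_applicable frac_rescued_full frac_rescued_partial rescued_fraction
#> 1          245         0.2530612            0.1959184        0.4489796
mean(as.character(calls$category) == study$truth$category)
#> [1] 0.9425
```

245 of the 400 features are confidently affected; 44.9% of them are
called rescued against the 40% planted (BIC selection at four time
points carries a small known upward bias, discussed in the vignette),
and 94% of all features receive exactly the planted category.

## Command line

A thin launcher over the same functions is installed at
`inst/cli/diffrhythm`:

```sh
diffrhythm simulate --out-dir sim --seed 4 --n-features 500
diffrhythm fit --matrix sim/matrix.tsv --samples sim/samples.tsv --out-dir fit
diffrhythm simulate --mode rescue --seed 6 --out-dir rs
diffrhythm rescue --untreated-matrix rs/untreated_matrix.tsv \
    --untreated-samples rs/untreated_samples.tsv \
    --treated-matrix rs/treated_matrix.tsv \
    --treated-samples rs/treated_samples.tsv \
    --reference WT --mutant strong --out-dir rescue
diffrhythm enrich --selection rescued.tsv --universe all.tsv --sets pathways.tsv --out-dir enrich
```

Every output table carries header comments with the package version and
a hash of the run configuration; `--config file.yaml` supplies defaults
that explicit options override, and identical configurations reproduce
identical output bytes.

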