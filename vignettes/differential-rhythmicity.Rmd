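---
title: "Differential rhythmicity analysis with diffrhythm: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential rhythmicity analysis with diffrhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffrhythm)
```

## The question and the model

Diurnal experiments routinely ask not just *is this gene rhythmic?* but
*does its rhythm differ between genotypes or treatments?* diffrhythm
answers the second question by harmonic (cosinor) regression with model
selection. For a feature measured in condition $c$ at Zeitgeber time $t$,
the working model is

$$ y_c(t) \;=\; \mu_c \;+\; \alpha_{g(c)} \cos\!\Big(\frac{2\pi}{T}t\Big)
   \;+\; \beta_{g(c)} \sin\!\Big(\frac{2\pi}{T}t\Big)
   \;[\;+\;\gamma_c\,t\;] \;+\; \varepsilon, $$

with a fixed period $T$ (24 h by default), Gaussian noise on the log2
scale, and a free mean $\mu_c$ per condition in *every* candidate model.
Candidates differ only in the map $g$: each condition is either
non-rhythmic ($\alpha=\beta=0$) or assigned to a rhythm group, and
conditions in one group share their $(\alpha,\beta)$ pair. The candidate
set is therefore every choice of a rhythmic subset together with a set
partition of that subset: $\sum_k \binom{C}{k} B_k$ models — 5 for two
conditions, 15 for three, 52 for four. `enumerate_models()` produces them
in a canonical order (flat model first, then by number of rhythmic
conditions, then lexicographically), and all outputs use structural
labels such as `WT=rhythm1|weak=rhythm1|strong=flat` rather than opaque
numbering; `model_alias_table()` lets users attach published numbers
where they know them, and none is ever guessed.

Fitted harmonics are summarized as peak-trough amplitude
$2\sqrt{\alpha^2+\beta^2}$ (log2 units), peak phase
$\operatorname{atan2}(\beta,\alpha)\,T/2\pi$ mapped into $[0,T)$ hours,
and the data-based relative amplitude $(\max-\min)/\text{mean}$ of the
per-time-point condition means. Formulas for these quantities sometimes
appear in the literature with radicals or division bars lost in
typesetting; the forms above are the only readings consistent with
"peak-trough amplitude" and "phase", and they round-trip exactly on
noiseless data.

## Selection: BIC, Schwarz weights, and what "n" means

Each candidate is fitted by ordinary least squares (QR decomposition,
batched across features that share a missingness pattern) and scored by

$$ \mathrm{BIC} = n\,\ln(\mathrm{RSS}/n) + k\,\ln(n), $$

where $k$ counts free parameters ($C$ means, $2$ per rhythm group, plus
trend slopes when enabled). Schwarz weights
$w_j = e^{-\Delta\mathrm{BIC}_j/2}\big/\sum_m e^{-\Delta\mathrm{BIC}_m/2}$
(computed after subtracting the minimum, so the best model always has
the largest weight) quantify the confidence that model $j$ is optimal
within the set; a feature whose best weight stays below the threshold is
called *ambiguous* and excluded from model-based categories.

Two choices here deserve explanation.

**What `n` counts.** With replicated designs, "sample size" is genuinely
ambiguous. Counting every replicate observation ties the BIC to the full
Gaussian likelihood, but at this package's target designs (4 time points,
2–3 replicates, 2–3 conditions) it makes the complexity penalty
$2\ln n$ barely larger than the median spurious improvement from giving a
shared rhythm group an extra coefficient pair: a Monte-Carlo check shows
each such "split" neighbour then beats the generating model for ~11% of
pure-noise draws, and features truly rhythmic everywhere get fragmented
into pseudo-distinct groups at a ~25% rate regardless of how small the
noise is. Counting *time points* instead — the distinct
(condition, time) cells, replicates being repeated measures at a cell —
raises the effective chi-square cutoff to ~6.5 and brings the spurious
split rate down to a few percent while leaving real differences (phase
gaps of hours) trivially detectable. `bic_n = "timepoints"` is therefore
the default, with `"observations"` available for users who prefer the
likelihood-faithful convention; the two agree on unreplicated designs.

**Thresholds.** The ambiguity threshold defaults to 0.3 for up to two
conditions and 0.5 for three or more (`default_bicw_threshold()`),
within the conventional 0.3–0.5 range tied to the number of conditions:
more conditions mean a larger candidate set, more near-neighbour models
and more opportunity for marginal overfits to win, so a stricter
confidence requirement is appropriate. Every entry point accepts an
explicit threshold, and the value used is recorded in all outputs.

## Metabolite mode: a drift term

Metabolite concentrations in developing larvae decline over the sampling
window for reasons unrelated to the clock. `fit_metabolites()` adds a
linear time term to every candidate design — per condition by default,
optionally shared or disabled (`trend_policy()`). The trend slope is
always a free parameter, not part of the zero/shared enumeration: the
candidate space stays the same 52-model family for four conditions, and
curated subsets can be supplied as an explicit candidate list (the
all-flat model is required, so the "no structure" hypothesis is always on
the table). With the trend disabled the designs reduce exactly to the
transcriptome pipeline.

## Rescue classification

Given a reference (wild-type) and a mutant condition, a feature is
*affected* in the untreated arm when the reference is rhythmic and the
mutant either lost the rhythm or carries a different parameter group. For
"different group" we additionally require the fitted peak-phase distance
or relative-amplitude gap to exceed its tolerance (0.5 h / 5% by
default, `rescue_tolerances()`): model selection at small $n$
occasionally splits a truly shared rhythm into two groups whose fitted
parameters differ by minutes, and such a split — reported as
`split_below_tolerance` — is not a biological alteration. Setting both
tolerances to zero restores the purely structural rule.

In the treated two-condition arm, both-rhythmic-shared is the
full-rescue pattern (conventionally lettered D in study reports) and
both-rhythmic-distinct the partial one (E). The decision rules
(`rescue_categories()`):

* treated shared → `rescued_full`;
* treated distinct after an untreated **loss** → `rescued_partial`
  (the rhythm is back, a residual difference remains);
* treated distinct after an untreated **alteration** →
  `rescued_partial` only if the phase distance *or* the
  relative-amplitude gap shrank by more than its tolerance, else
  `not_rescued_Estar`;
* anything else (including an ambiguous treated assignment) →
  `not_rescued_other`;
* features not affected → `not_applicable`.

Rescue percentages (`rescue_summary()`) are computed over features
confidently affected untreated *and* confidently assigned treated;
features ambiguous in either arm are excluded from the denominator and
reported separately. Decreasing the treated-arm phase gap can only move
a feature toward rescue, never away — a monotonicity the test suite
checks explicitly.

## Enrichment statistics

Over-representation uses the exact upper-tail hypergeometric probability
$P(X \ge k)$ (`hypergeom_upper_tail()`, cross-checked in the tests
against exhaustive subset enumeration for every universe up to size 12)
with Benjamini–Hochberg correction across sets and a 0.05 significance
flag. `cooccurrence_enrichment()` counts a feature as a hit only when it
carries at least one hit of *every* motif class — e.g. an E-box and a
glucocorticoid response element in the same promoter — and tests whether
such double-positive promoters concentrate in a gene set. Motif scanning
itself is out of scope; the function consumes a per-feature hit table
from any scanner.

## The synthetic cohort generator

`simulate_matrix()` emulates the study design the package targets: three
genotypes (wild-type and two mutant alleles) sampled at ZT 3, 9, 15, 21
with two replicates for transcriptome mode; four genotype×treatment
conditions at five time points spanning 24 h (ZT 3–27) in triplicate
with a declining baseline for metabolite mode. Defaults: peak-trough
amplitude 2 and noise sd 0.1 on the log2 scale (an amplitude-to-noise
regime typical of confidently rhythmic transcripts after variance
stabilization), baselines uniform on 6–10 log2 units, phases uniform
over the day, drift slopes uniform on −0.08 to −0.02 log2/h. When one
feature carries several distinct rhythm groups their phases are drawn at
least 4 h apart — "distinct parameters" is only a recoverable truth when
the parameters actually differ, and sub-hour separations are not
resolvable at four time points. The generator writes $A/2$ as the cosine
coefficient so the truth tables record peak-trough amplitudes, matching
`amplitude()` exactly.

`simulate_rescue_study()` plants a known rescue structure across two
arms sharing feature ids: 60% affected features, of which a configurable
fraction is rescued (60% fully, 40% partially), and the rest split 30%
persistent-divergent (the E\* pattern: genotype baselines, amplitudes
and the phase offset reused across arms so "no reduction of differences"
holds exactly in the noise-free signal) and 70% still arrhythmic.

What the generator does *not* emulate: count-level sampling noise,
heteroskedasticity across expression levels, correlated features,
batch effects, missing-at-random structure beyond user-injected `NA`s,
or any treatment effect on baselines. Passing recovery tests therefore
demonstrate correctness of the machinery under the stated noise model,
not performance on raw sequencing data.

## Numerical choices and degenerate inputs

* Perfect fits: the BIC uses `max(RSS, eps)` with
  `eps = 1e-12 (n Var(y) + 1)`, so noiseless synthetic data stay finite
  and comparable across candidates.
* Ties in Schwarz weights break toward the earlier model in enumeration
  order — the simpler model, since enumeration orders by the number of
  rhythmic conditions.
* Rank-deficient designs (too many missing values, collinear columns)
  flag the feature as unfittable instead of aborting a run; all-constant
  features land on the flat model.
* Missing values are dropped per fit with both `n` conventions adjusted.
* A zero harmonic has no phase; `phase_hours(0, 0)` is `NA`, and `NA`
  phases propagate through circular distances rather than erroring.
* Weights are computed after subtracting the minimum BIC, so arbitrarily
  large common offsets cannot overflow.

## Problem sizes in the test suite

The recovery checks run at the design sizes above: 1000-feature cohorts
for model/parameter recovery and for the planted-rescue study, 500
random instances for the least-squares oracle comparison, and universes
up to $N = 12$ for the exhaustive hypergeometric check. On these sizes
the whole suite completes in a few minutes on a single core, with the
batched per-model QR solver doing the heavy lifting.

## Known limitations

* One fixed period per run; no multi-harmonic or period-estimation
  support.
* BIC-based selection at four time points has an irreducible
  false-split rate of a few percent per neighbouring model; downstream
  summaries that count "any rescued" inherit a corresponding upward
  bias of a few percent, which the ambiguity threshold and the
  effect-size guard reduce but cannot eliminate. Treat rescue
  percentages as estimates with that systematic component in mind.
* Ordinary least squares assumes independent homoskedastic noise;
  autocorrelated or weighted designs are out of scope.
* The relative amplitude is computed from per-time-point means of the
  data and is therefore noisier than the fitted amplitude; it is kept
  because it is the conventional scale for cross-condition comparisons.
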