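---
title: "Discovering microbiome predictors of long-term weight-loss success: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering microbiome predictors of long-term weight-loss success: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microwl)
```

## The problem

Nonsurgical weight-loss programs succeed durably for some patients and not
for others. If the baseline gut microbiome carries predictive signal, a
small panel of taxa measurable by qPCR could inform therapy choice. The
statistical obstacle is the regime: a cohort of n ≈ 15 patients against
p ≈ 100 relative-abundance predictors, where any single selection method is
fragile and chance correlations are everywhere.

`microwl` implements a defensive strategy for this regime: three largely
independent selection avenues are run in parallel and fused into one
evidence score, and the resulting sparse linear models are reported with
honest small-sample diagnostics (AICc, adjusted R², cross-validated R² from
averaged out-of-fold predictions, per-patient classification against a 10%
relative-weight-loss threshold).

Two responses quantify outcome: relative weight loss after two years
(RWL, percent of baseline body weight; the persistent-success group is
defined by RWL ≥ 10%) and the change in body-mass index over the same
period (delta BMI, kg/m²).

## Data reduction

Raw taxa-by-sample tables (counts or relative abundances, genus or species
level) are reduced before modeling:

1. a blacklist of three thermophilic genera (*Caldicellulosiruptor*,
   *Thermaerobacter*, *Thermobacillus*) is removed from genus tables —
   these are almost certainly read-binning artifacts, not gut residents;
2. the table is cut to its `n_keep` most abundant taxa (102 for genera,
   106 for species in the reference setting), ranked by mean relative
   abundance across samples; rare taxa carry most of the measurement error
   and essentially no modeling value;
3. rows are re-closed to proportions over the retained taxa.

Whether to re-close or to keep the original relative abundances is not
decidable from the published account; re-closure is the default and the
alternative is available via `reduce_to_top(close = FALSE)`. The ordering
statistic (mean abundance vs prevalence) is likewise configurable; mean
abundance is the default because coverage — the retained fraction of total
mass — is the published justification for the cut.

## Avenue I: correlation screening

Every taxon is correlated with both responses (`correlate_all`,
`screen_taxa`). Pearson's r is the default because everything downstream is
a linear model; Spearman is available by flag. The screening result enters
the final score through a banded *correlation class*: the weaker of the two
absolute correlations, rounded to a full percent (half away from zero, so
44.5% rounds to 45%), mapped through half-open bands
[45, 50) → 0.5, [50, 55) → 1, [55, 60) → 1.5, ≥ 60 → 2, signed by the
common direction of the two correlations; taxa whose two correlations
disagree in sign get class 0. "Strong correlation to both responses" is
operationalized as the minimum of the two — each response must clear the
band on its own.

A subtlety about signs: delta BMI as a raw *change* is negative for
successful patients, so a success-associated taxon correlates positively
with RWL and negatively with the change. The published candidate tables
carry one common sign per taxon, which is only coherent when both responses
point in the weight-loss direction. The pipeline therefore screens against
the BMI *reduction* (−delta BMI) by default (`dbmi_direction = "loss"`);
the raw-change convention remains available.

## Avenue II: elastic-net stability selection

`run_selection` repeats, many times, the full tuning loop of a
cross-validated elastic net (glmnet backend): draw a random fold
assignment, cross-validate the penalty λ over a fixed path at a fixed
mixing parameter α, refit on all data at the CV-optimal λ (minimum mean
squared error, not the 1-SE rule), and record which taxa have nonzero
coefficients. A taxon's *occurrence* is the percentage of repeats in which
it was selected. Defaults are α = 1 (lasso) with 5 folds and 1000 repeats —
1000 gives 0.1% occurrence granularity, matching the precision at which
occurrences are conventionally reported; the α × folds grid
{0.25, 0.5, 0.75, 1} × {3, 5, 8, 15} is exposed via `selection_grid`.
Candidates are taxa reaching 1% occurrence for at least one response
(`filter_candidates`).

With n = 15, fold counts of 8 or 15 necessarily produce single-sample test
folds; these are legitimate (15-fold is leave-one-out) and only empty folds
are an error.

## Avenue III: Monte-Carlo model search

`sample_models` draws a large pool (default 100,000 per stage) of distinct
OLS models with term counts uniform on 1..4 and term sets uniform within
count — when the total number of subsets is smaller than the pool size the
enumeration is exhaustive instead. Each model is scored by the small-sample
AICc with the parameter count including intercept and error variance
(a 4-term model has k = 6). `compute_index` aggregates the pool into a
per-taxon importance index from three components:

* **A** — how often the taxon appears among the best 5% of models by AICc;
* **B** — the mean Akaike weight (`exp(−ΔAICc/2)`, normalized over the
  pool) of the models containing it;
* **C** — the stability of its coefficient sign across containing models,
  multiplied by its overall selection frequency.

Each component is min–max scaled, combined with weights (A, B, C) — the two
published weightings are (0.60, 0.20, 0.20) and (0.45, 0.10, 0.45) — and
normalized so the stage's best taxon scores exactly 1. The precise
component definitions were not published (they live in an unavailable
appendix); the definitions above were chosen to be AICc-driven, stable and
interpretable, and they are deliberately isolated behind `compute_index` so
alternatives can be swapped in. `reduce_and_iterate` then repeatedly keeps
the top-m taxa and re-runs the search along a reduction schedule
(102 → 44 → 23 → 15 → 7 for genera at weighting 1); the schedules are
configuration, not logic, because the published schedules differ between
weightings with no stated rule. Per-taxon ranks are averaged across
weightings (and responses) by `average_ranks`; a taxon absent from a final
list keeps a missing marker rather than an imputed rank.

## Fusing the avenues

`final_score` combines, per taxon,

```
score = 1·max(0, 7 − avg_rank_full) + 1·max(0, 7 − avg_rank_final)
      + 3·elastic_net_selected + 1·|correlation_class|
```

with missing ranks contributing zero. Ranks at or beyond the ceiling of 7
clamp to zero rather than going negative — the published scores contain no
negative terms and the final lists have at most 8 entries. A rank equal to
7 and a missing rank are treated identically (both contribute 0); nothing
in the published arithmetic distinguishes them. Taxa selected only by the
elastic net still receive a score (weight 3 puts them at 3 plus any
correlation-class credit). The report keeps taxa with score ≥ 2; the full
table is always written alongside.

## Prediction models

From the fused candidate list, `best_k_term_models` searches all
`choose(m, k)` subsets for k = 1..5 exhaustively — at m ≤ 8 this is at most
56 fits per k, so no stochastic search is needed — and returns the best
model per size by AICc (ties by smaller residual sum of squares, then
lexicographic term order). `cv_r2` estimates out-of-sample R² by repeated
random fold assignment (default 200 repeats, stratified by outcome group so
no training fold loses a whole group), averaging each patient's out-of-fold
predictions over repeats before computing
R² = 1 − Σ(y − ŷ)²/Σ(y − ȳ)²; 15 folds at n = 15 is leave-one-out and
deterministic. `classify_predictions` labels each patient correct(+),
correct(−), overpredicted or underpredicted against the 10% RWL threshold,
inclusive at the boundary. The classification threshold for delta BMI was
never published; the RWL table is the canonical surface, and a user-set
threshold covers the delta-BMI case.

## Ordination and group comparisons

`clr_transform` maps proportions to centered log-ratios (pseudocount: half
the smallest nonzero value, applied only when zeros are present — the
reference analysis does not state its zero handling). `pca_scores` runs
column-centered PCA; on clr data, score-space distances are Aitchison
distances. `permanova` implements the one-factor pseudo-F test directly
from the squared-distance partition with seeded label permutations —
re-implemented rather than wrapped precisely so the permutation scheme and
seed are controlled; the vegan implementation serves as an independent
oracle in the test suite. `groupwise_tests` runs two-sided Mann–Whitney
tests per taxon with Benjamini–Hochberg q-values (reporting threshold
q < 0.1). `zscore` standardizes with the sample (n − 1) standard deviation.

## The synthetic cohort

`generate_cohort` builds a cohort with the statistical structure the
analysis assumes, so that every stage is testable offline:

* **Outcomes.** RWL is drawn per group — 8 patients from N(18.2, 3²), 7
  from N(0.2, 3²), the group means matching the reference cohort — and
  labels are then re-derived from the 10% rule. The within-group SD of 3%
  is a choice (the source reports only means): it keeps the groups
  separated at the threshold, as the real groups were. delta BMI is
  −(baseline BMI/100)·RWL plus N(0, 0.5²) noise, with baseline BMI from
  N(42.4, 6²); weight loss therefore lowers BMI.
* **Composition.** 1020 taxa with log-normal abundances (shared log-SD 1)
  whose means decay as rank^(−2). The exponent 2 is deliberately steeper
  than a casual reading might suggest: it is what makes the top 102 of
  1020 taxa cover ~99% of the mass, the property the data reduction relies
  on (an exponent near 1.2 leaves them at ~79%). Counts are multinomial at
  a configurable depth (default 10⁶, emulating deep shotgun assignment).
* **Planted signal.** Each planted taxon's *closed share* responds
  linearly to a rotation between the standardized outcome and a noise
  contrast: share ∝ mean·(1 + 0.3·latent). The rotation weight is
  calibrated by root finding so the realized correlation with RWL on the
  closed composition hits the target; unattainable targets raise an error
  instead of being clipped. The noise contrasts are built to sum to zero
  across the planted set, so the outcome is — up to closure and count
  noise — a *linear combination of the planted proportions*. This is a
  deliberate design choice: injecting the signal purely in log space and
  calibrating only marginal correlations caps the planted set's joint R²
  on the proportion scale near 0.55 (the exp/closure nonlinearity and the
  shared closure denominator decorrelate the columns from the outcome),
  which contradicts both the reference analysis (best 3–4-term models with
  adjusted R² of 82–93%) and the premise of any recovery test. Planting on
  the proportion scale reproduces the world the method is claimed to work
  in: a handful of taxa whose proportions linearly explain most of the
  outcome, buried among ~100 compositional noise taxa.

What a green recovery test establishes, therefore, is that the pipeline
finds linearly-predictive taxa amid realistic compositional noise at
n = 15 — not that such taxa exist in any particular real cohort, and not
that the method is robust to nonlinear or interaction structure, which the
generator does not emulate. Other omissions: no sequencing-read simulation,
no taxonomy misassignment, no enterotype structure, no longitudinal change.

## Numerical choices

* AICc: `n·log(RSS/n) + 2k + 2k(k+1)/(n−k−1)` with k = terms + 2; additive
  constants are dropped (only differences matter). Models with
  n − k − 1 ≤ 0 get +∞. Exact fits are floored at RSS = 10⁻¹² with a
  warning.
* Singular model subsets are skipped (pool) or reported with the collinear
  term named (`fit_ols`).
* Correlation-class rounding is half-away-from-zero, so a 44.5% minimum
  correlation lands in the 0.5 band.
* Determinism: every stochastic stage takes a seed; the pipeline derives
  per-stage seeds from the global seed by fixed offsets, so a rerun with
  the same config is byte-identical.
* Ties: reduction keeps ties by taxon id; model-search ties break by RSS
  then lexicographic terms; rank ties get midranks.

## Known limitations

The Monte-Carlo index components approximate an unpublished definition; the
published index *values* are not reproducible, only the qualitative
behavior (and the exact fused-score arithmetic downstream of the printed
ranks). Headline statistics of the reference cohort (AICc 74.9, adjusted
R² 82–93%, CV R² 67–85%, PERMANOVA p = 0.076/0.002) depend on per-patient
abundances that were never published and are out of reach by design; the
test suite replaces them with property-based checks on the synthetic world.
At n = 15, all reported fit statistics — real or synthetic — should be read
as candidate-screening evidence, not validated predictive performance.
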