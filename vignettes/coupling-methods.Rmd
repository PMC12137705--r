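---
title: "Structure-function coupling and NMA prediction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling and NMA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `couplemap`,
the parameters that matter, the synthetic cohort generator that stands in
for restricted neuroimaging data, and the design decisions taken where the
methodology leaves genuine freedom.

## 1. The coupling model

A participant's structural connectome is an N×N symmetric, non-negative,
zero-diagonal matrix W of connection weights (streamline-density-like,
unitless). Four predictor matrices are derived from it:

* **Cosine similarity (CoS).** For regions i and j, the cosine of the angle
  between their connection profiles (columns of W). By default the entries
  belonging to the pair itself (rows i and j) are removed from both
  profiles, so a single strong direct edge cannot trivially inflate the
  similarity of its endpoints; `exclude_pair = FALSE` restores the plain
  column cosine for sensitivity analyses. Entries lie in [0, 1]; regions
  with zero strength get a zero row/column with a warning.
* **Path length (PL).** Dijkstra distances on the edge-length graph
  L = 1/w (default) or L = −log(w / max w) (configurable): strong
  connections are short. Distances are then *negated* so that, like all
  other predictors, larger values mean easier communication.
* **Communicability (G).** The matrix exponential of the
  strength-normalized weights, exp(D^−1/2 W D^−1/2), D = diag(row sums).
  The normalization is essential for streamline-density-scale weights,
  where exp(W) overflows; it is also the form established for weighted
  brain networks. Computed by symmetric eigendecomposition (the truncated
  power series serves as the independent test oracle, never as the
  implementation).
* **Search information (SI).** For the shortest path π(i→j) on the length
  graph, SI(i→j) = −log2 Π p(u→v) with p(u→v) = w_uv / strength(u): the
  information needed to steer a random walker along the path. Because SI is
  directed, the matrix is symmetrized by averaging the two directions, then
  negated.

**"Inversion" as negation.** PL and SI must be adjusted so that high values
mean "close/easy" before correlating them with FC. We implement the
adjustment as negation (×−1) rather than elementwise reciprocal: negation
is monotone, keeps zeros and sentinels well-behaved, and leaves coupling
correlations identical up to sign. The reciprocal is available via
`analysis_config(invert = "reciprocal")` for comparison.

**Unreachable pairs.** Disconnected pairs receive a sentinel of 1.5× the
largest finite distance (PL) or largest finite symmetrized SI before
negation, with a warning, preserving matrix shape. Synthetic cohorts are
generated connected, so sentinels arise only for pathological inputs.

**Shortest-path ties.** SI needs *the* shortest path; with continuous
weights ties have probability zero, but for reproducibility on degenerate
inputs the internal Dijkstra breaks equal-distance ties by the smallest
predecessor index (and settles equally distant nodes in index order). PL
itself uses igraph's Dijkstra — distances are tie-invariant — and the two
implementations are cross-checked in the tests together with an exhaustive
simple-path enumeration oracle.

Region-specific coupling r_C is the Pearson correlation between column i
of a predictor matrix and column i of the condition-specific FC matrix over
the N−1 off-diagonal entries. The diagonal is excluded everywhere: FC
self-correlation is undefined after the Fisher transform (atanh(1) = ∞).
Degenerate (constant) profiles yield r_C = 0 with a warning rather than
NaN, keeping downstream means defined.

## 2. Descriptive characterization

Brain-average coupling (mean over regions, then over measures or
conditions) is compared across conditions with a one-way within-participant
ANOVA. We use the multivariate-model route (`anova.mlm`) with Mauchly's
sphericity test and apply the Greenhouse–Geisser corrected p-value whenever
Mauchly rejects at 0.05 — standard repeated-measures practice. Post-hoc
pairwise comparisons use model-estimated marginal means from a
random-intercept mixed model (lme4 + emmeans) with Tukey adjustment by
default (Bonferroni configurable); the upstream methodology reports
marginal-means contrasts without naming a correction, so the default is a
package choice.

The regional pattern of a condition is built by assigning each region the
measure with the highest mean squared coupling (R²) across participants
(ties, essentially impossible with continuous data, go to the first measure
in CoS, PL, G, SI order and are logged), then averaging the winning
measure's individual R² values. Pattern similarity between conditions is
the Pearson correlation of these N-vectors; rest-vs-task similarity is
tested with a two-sample z-test on the Fisher-transformed pair
correlations (rest–task pairs vs. task–task pairs), using 1/(N−3) as the
per-correlation variance.

Task adaptation is quantified as absolute regional differences: each task
vs. rest (task-specific), rest vs. the mean task pattern (task-general),
and each task vs. the mean of the remaining tasks (task-specific relative
to a task-general baseline, leave-one-task-out). For the per-task kinds we
also report a signed percentage of each task's mean adaptation relative to
the grand mean over tasks, 100·(m_t − m̄)/m̄. The percentage baseline is a
package convention — the raw map means are always reported alongside, and
no result in this package depends on the convention.

## 3. Association and prediction

Partial correlations residualize both variables on the covariates (age,
gender 0/1, signed continuous handedness, condition-specific mean
framewise displacement) with an intercept, and use t with n−2−k degrees of
freedom. Significance of brain-average associations is controlled with
Bonferroni over the four measures (0.05/4 = 0.0125).

**B-NMA.** Within each cross-validation training set, r_P(region, measure)
= partial correlation between coupling and phenotype. The positive mask
takes the argmax over measures per region, the negative mask the argmin.
If a region has no positive (or no negative) association at all, the
argmax/argmin is still used — excluding regions would change the feature
dimension fold-by-fold — and the condition is flagged per region
(`forced_positive`/`forced_negative`). Features are the mean masked
coupling per participant; OLS on raw phenotype scores (covariates enter
only through the r_P selection, which is where the upstream methodology
applies them) predicts the held-out fold. Per repetition, fold predictions
are concatenated before correlating with the observed scores —
the dominant convention in connectome-based prediction and stable for
n/5-sized folds — and performance is the mean r over repetitions (default
100; R² is reported both as the square of that mean and as the mean
per-repetition r²; both appear in `prediction_result`).

**E-NMA** builds the two features per task condition (rest excluded) and
fits a single OLS on all 2·n_tasks features, guarding against saturated
training folds.

**Permutation inference.** Phenotype scores are permuted across
participants while covariates stay attached to the imaging data, which
preserves the confound structure under the null; the full pipeline
(mask selection + fitting) is re-run per permutation, and
p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm) (add-one smoothing avoids p = 0).
Permutation runs default to 10 CV repetitions instead of 100
(`n_perm_repetitions`), because 1000 permutations × 100 repetitions is
cluster-scale; the fold scheme is shared across permutations, and the
per-fold covariate projections and residualized coupling matrices are
precomputed once, so each permutation costs one matrix-vector product per
fold and condition. Model differences are tested by comparing |Δr| observed
to |Δr| under jointly permuted phenotypes. Cross-sample generalization
freezes each training fold's masks and coefficients (5 models ×
n_repetitions splits) and applies them unchanged to a replication cohort;
significance permutes the replication phenotype against the frozen
predictions.

**Determinism.** All resampling derives from `rng_seed` via per-repetition
seeds; identical configurations reproduce results bitwise.

## 4. The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with group-level structure (node geometry, template SC, regional gradient,
measure preferences, rest pattern) drawn from a *structure seed* and
participant-level data from a *cohort seed*, so replication cohorts share
the group structure.

* **SC.** Nodes sit in a unit cube; edge probability decays exponentially
  with distance (calibrated to the target density, default 0.25); weights
  are log-normal (heavy-tailed, positively skewed) and distance-attenuated;
  connectedness is guaranteed by adding the Euclidean minimum spanning
  tree. Participants perturb the template weights multiplicatively
  (log-normal sd 0.2), preserving topology.
* **FC.** Column i is built in the span of the participant's own predictor
  columns: a *preferred direction* (the region's preferred measure column
  blended 50/50 with its measure-unique component, i.e. the part orthogonal
  to the other three measures — the blend controls the winner/runner-up R²
  gap, ≈ 0.2 at defaults), scaled to a target coupling level, plus
  Gaussian noise. The target level combines a regional gradient (0.5–0.85,
  mimicking the unimodal→multimodal axis), a global condition offset (rest
  +0.05, one low task −0.05 by default), a rest-specific pattern component,
  and a stable participant offset (sd 0.02) that generates realistic
  between-participant brain-average variance (per-participant SD ≈ 0.02 at
  defaults, the regime in which the condition contrasts operate). Columns
  are assembled and the matrix symmetrized by averaging, which blurs and
  attenuates all planted effects by a factor ≈ 0.5–0.9 — the recovery tests
  operate on what the pipeline actually sees, not on the pre-symmetrization
  ideal.
* **Planted associations.** Each signal region adds a measure-unique
  (orthogonalized) component whose weight is a latent standard-normal
  deviation d; orthogonalization confines the phenotype signal to the
  planted measure so mask recovery is identifiable. The phenotype is
  g = Σ sign·effect_r·d + √(1−Σeffect_r²)·ε, standardized — so
  corr(g, d_region) equals the planted effect_r exactly and the total
  planted signal is R² = Σ effect_r². An optional per-row condition
  restricts a signal to one task (used to emulate task-specific
  information for the task-combined model). Realized coupling-phenotype
  correlations are attenuated to ≈ 0.8·effect_r by FC noise and
  finite-N coupling estimation.
* **Covariates** are drawn with weak configured correlations to g (age
  0.1, gender 0.05, motion −0.15 by default) — enough to exercise the
  partial-correlation machinery without dominating it.

What the generator does *not* emulate: spatial autocorrelation of FC noise,
hemispheric structure, global signal artifacts, motion-coupled FC
corruption, or biophysical dynamics. Passing tests therefore demonstrate
correctness and calibration of the *pipeline*, not robustness to every
empirical artifact of real fMRI data.

## 5. Problem sizes and numerical choices

The test suite runs at desk scale: 60 regions and cohorts of 200–500
participants, with 100-repetition simulation loops where recovery rates
are asserted, 100-permutation tests at 10 CV repetitions, and 10–25
repetitions per fitted model inside simulation loops. These sizes were
chosen so the planted effects are comfortably identified (recovery
probabilities near 1 under the configured conditions) while the whole
suite completes in tens of minutes; a full-cortex configuration
(358 regions, 500+ participants, 100 repetitions, 1000 permutations) is a
matter of changing `generator_config`/`analysis_config` arguments.

Numerical conventions worth knowing:

* Matrix symmetry is enforced with a 1e-6 asymmetry tolerance
  (symmetrize-by-averaging below it) to absorb I/O round-off; CSV output
  uses 17 significant digits so round trips are bitwise.
* Correlations are clipped to [−1, 1]; degenerate denominators (constant
  profiles, zero-variance predictions) map to r = 0 with a warning or log
  entry rather than NaN.
* Argmax/argmin ties in masks and best-measure maps break toward the
  configured measure order (CoS, PL, G, SI) and are logged.
* The E-NMA refuses to fit when 2·n_tasks + 1 ≥ training-fold size.

## 6. Known limitations

* The repeated-measures machinery expects complete data (every participant
  in every condition); participants missing a condition are dropped when
  the coupling table is built.
* The two-sample z-test on pattern correlations treats the condition-pair
  correlations as independent, which they are not exactly; it matches the
  coarse inferential use it is put to.
* Frozen-model transfer assumes the replication cohort uses the same
  parcellation (region count and order) and measure set.
* With `invert = "reciprocal"`, PL/SI sentinel handling maps unreachable
  pairs to 0 ("infinitely far"), which is sensible but changes the value
  scale; the default negation is used throughout the tests.
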