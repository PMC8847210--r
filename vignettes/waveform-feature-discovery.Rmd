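---
title: "Discovering discriminative principal components in waveform cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering discriminative principal components in waveform cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical movement analyses compare two groups — here, subjects after
anterior cruciate ligament reconstruction (ACLR) against uninjured
controls — on ensembles of biomechanical waveforms: joint angles, joint
moments and muscle forces, each recorded over a movement phase (e.g. the
landing phase of a single-leg hop, from foot strike to peak knee flexion)
and time-normalized to 101 phase points. Comparing hundreds of correlated
curves point by point is both statistically hopeless and clinically
unreadable. `pcwave` instead compresses each variable's trial ensemble into
a few *principal components* (characteristic waveform shapes), then finds
the minimal set of component scores that best distinguishes the groups,
and produces the artifacts needed to read each selected score as a
movement pattern.

## The model and its stages

### Trial weighting

Subjects contribute unequal numbers of repeated trials. Pooling all `n`
trials as rows would let prolific subjects dominate every cross-trial
statistic, so each trial of a subject with `q_S` trials receives the
factor `tau_i = 1/q_S`, normalized across rows to weights
`w_i = tau_i / sum(tau)`. Every subject then carries total weight
`1/(number of subjects)` exactly; duplicating a subject's trials changes
nothing downstream (a property the test suite checks numerically).

### Weighted-correlation PCA

For each variable, with `X` the `n x p` trial-by-phase matrix, the
pipeline eigen-decomposes the *trial-weighted* correlation matrix `R`
(weighted means `mu_k = sum_i w_i x_ik`, population-style weighted
covariances, normalized to unit diagonal). Scores are `Z = X_std U`, where
`U` holds the eigenvectors of `R` and `X_std` is `X` standardized
column-wise by the weighted mean and weighted SD. The standardization step
deserves a note: with `Z = X U` on raw data the score columns would *not*
be mutually uncorrelated under the weights, which is the property the
decomposition is used for; standardizing restores exact weighted
orthogonality of the scores, and we treat it as the only self-consistent
reading of a correlation-matrix PCA. Each eigenvector's sign is fixed by
making its largest-magnitude coefficient positive — signs of eigenvectors
are otherwise arbitrary, and a deterministic convention keeps runs and
downstream `|t|`-based rules reproducible.

Weighted variances use the population-style divisor `sum(w) = 1` (no
degrees-of-freedom correction): the weights are normalized design weights,
not frequency counts. The testing/effect-size layer, by contrast, uses
ordinary `n - 1` sample SDs, since there the trials enter unweighted.

### Horn's parallel analysis

Components are retained per variable when their eigenvalues exceed the
95th percentile of eigenvalues from `N = 1000` random standard-normal
matrices of the same `n x p` dimensions (column correlation, `p x p` —
matching the dimension of `R`). Retention is a contiguous prefix: the
largest `k` such that ranks `1..k` all beat their rank-wise thresholds;
a late rank is never kept above a dropped one. Percentiles interpolate
linearly between order statistics (type-7 quantiles); with `N = 1000` the
estimator choice is visible in the third decimal, so it is pinned here.
Thresholds depend only on `(n, p)` and are computed once per cohort and
shared across variables — the random replicates are i.i.d., so this is a
pure compute saving. The random draws are unweighted; the observed
(weighted) eigenvalues are compared against unweighted noise thresholds.

### Weiss–Indurkhya screening

Each retained score column is compared between groups with Welch's
unequal-variance t-test (trial-level `n`); features with `|t| >= 2.0`
survive. The absolute value matters: score signs follow the eigenvector
sign convention, so a one-sided rule would encode an arbitrary choice.
The cutoff corresponds to a two-sided tail probability of about 0.046 at
the cohort-scale degrees of freedom (`wi_screening_level(2, 450)`).
No multiplicity correction is applied at this stage; the final
confirmation stage tightens the level instead.

### Sequential forward selection consensus

The surviving features enter a greedy wrapper: starting from the empty
set, the feature whose addition most lowers the 10-fold cross-validated
misclassification rate of a Gaussian naive Bayes classifier is added,
*only if* it strictly lowers the rate (ties do not admit a feature —
under plateaus an accept-on-equal rule would grow sets without bound),
stopping otherwise or at 10 features. Folds are stratified by group; with
~150 trials in the smaller group and 10 folds, unstratified folds can go
single-class on unlucky seeds. The CV rate pools held-out errors over all
folds rather than averaging per-fold rates, making it invariant to
unequal fold sizes. Each run draws one fold assignment shared by all its
candidate evaluations; because the naive Bayes log-posterior is additive
over features, per-fold per-feature log-densities are precomputed once
per run and candidate subsets are scored by summing slices.

Because fold randomization makes single runs unstable, the selection is
repeated (default 1000 runs; 100 is the documented fast mode used in the
package's own test benchmarks) and the 10 most frequently selected
features form the consensus *main features*. Frequency ties at the cut
are broken by earlier mean within-run selection position, then
lexicographic feature id, and the report flags when a tie-break fired.
Features never selected are excluded even if fewer than 10 remain.

The Gaussian class-conditional model uses empirical priors, per-feature
class means and `n - 1` variances with a floor of `1e-9` times the
feature's pooled training variance (a fold in which a class is nearly
constant on a feature must not produce infinite densities). Exact
posterior ties predict the case class — deterministic and measure-zero
for continuous scores.

### Confirmation, effect sizes, associated features

Main features are re-tested with Welch's t at `alpha = 0.001` (they
already passed the 0.046-level screen) and reported with Hedges' g:
pooled-SD standardized difference times the small-sample correction
`J = 1 - 3/(4(n1 + n2) - 9)`. Associated features are retained, non-main
components correlating with a main feature at `|rho| >= 0.5` (moderate up
to 0.7, strong above; inclusive lower bound), with a significant
correlation test (`alpha = 0.05`, t with `n - 2` df) and their own group
separation `|t| >= 2.0`.

For interpretation, each main feature yields: mean ± SD waveforms of the
pooled trials in the upper (score ≥ 75th percentile) and lower (≤ 25th)
score quartiles — type-7 percentiles, inclusive membership, which on
distinct scores gives exactly `ceiling(n/4)` trials per quartile; the
eigenvector coefficient curve; and the explained-variance curve, the
squared trial-weighted correlation between each phase column and the
score column (weighted, for consistency with the PCA; the squared
correlations of one column across all components then sum to 1). The
case group is reported as lying nearer the upper or lower quartile
according to its mean score.

## The synthetic cohort generator

No public data accompany the motivating study, so the generator is a
first-class module providing ground truth. Each variable is a smooth
grand-mean curve plus `M` orthonormal smooth modes (orthogonal polynomial
basis); each trial draws one amplitude per mode as subject random effect
plus trial noise, and a discriminative `(variable, mode)` pair shifts the
case group's amplitude by a configured standardized effect. Injecting
effects on *mode amplitudes* (not raw samples) makes ground truth align
with principal components by construction, which is exactly what recovery
tests need. Gaussian effects and noise match the naive Bayes working
model.

Defaults emulate the motivating cohort: 66 case and 32 control subjects
with 3–6 trials each (expected totals near 300/145 trials, the ~2:1
ratio of the 452-trial cohort), 30 variables, 101 phase points, 4 modes
per variable, and 5 discriminative pairs with effects 0.8, −0.6, 0.9,
0.7, −0.5 (magnitudes spanning 0.5–0.9). Mode amplitude scales decay
geometrically at rate 1.65, giving eigenvalue profiles (~66/24/8/3% of
variance) resembling published landing-phase variance tables, with gaps
wide enough that principal-component rank equals injected mode rank and
all modes clear the parallel-analysis threshold at this `n`. The
subject/trial amplitude SD split (0.6/0.8) puts ~36% of amplitude
variance at the subject level, a realistic intra-class correlation for
repeated functional tasks that exercises the trial weighting
meaningfully.

What the generator does *not* emulate: biomechanical physics, joint
coupling, non-Gaussian or heteroscedastic noise, phase misalignment
between trials, and measurement noise uncorrelated with the modes.
Passing recovery tests therefore show that the pipeline finds the
structure it assumes, not that it is robust to everything real motion
capture produces.

The null-calibration configuration (`paper_scale_config(null_cohort =
TRUE)`) zeroes every effect *and* the subject random effect. The reason
is statistical, not cosmetic: the screen treats trials as independent
observations, so with subject-level correlation present the trial-level
Welch test is anti-conservative and the screen's nominal ~4.6% null
retention holds only for independent trials. This is also the pipeline's
main known limitation on real repeated-trials data — the trial weighting
equalizes subjects inside the correlation matrix, but the testing layer's
`n` is the trial count, and within-subject correlation inflates its
false-positive rate. A subject-level or mixed-model testing layer would
be the principled extension.

## Numerical choices and degenerate inputs

- Time normalization is piecewise-linear interpolation onto 101 points
  spanning the recorded interval, endpoints preserved exactly: monotone
  and overshoot-free, appropriate for already-smooth motion curves.
- A variable with any zero-weighted-variance phase column is rejected as
  degenerate rather than patched.
- Eigenvalues are clamped at zero against `-1e-16`-scale round-off; ties
  keep the eigensolver's order under a stable descending sort.
- A trial missing any variable is rejected whole: the pooled pipeline
  requires identical row alignment across variables.
- Cohorts must contain both groups, and every trial of a subject must
  carry one group label.

## Problem sizes in the package's own benchmarks

The bundled tests run the full pipeline on generated cohorts at the
emulated scale (about 450 trials, 30 variables, 101 phase points) with
parallel-analysis replicates reduced to 200 and selection iterations to
100 — sizes chosen so the whole suite completes in a few minutes while
the Monte-Carlo stages stay well-resolved; module tests use smaller
cohorts (tens of trials, ≤ 4 variables, 21–31 phase points). Production
analyses should use the defaults (`N = 1000`, 1000 iterations).

## Worked example

```{r example}
library(pcwave)

gen <- generate_cohort(paper_scale_config(seed = 42))
report <- run_pipeline(gen$cohort,
                       pipeline_config(pa_replicates = 200,
                                       sfs_iterations = 100, seed = 7))
print(report)
report$selection$main_features
render_report(report, "report_out", figures = TRUE)
```
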