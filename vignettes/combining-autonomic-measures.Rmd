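---
title: "Combining autonomic threat-conditioning measures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining autonomic threat-conditioning measures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearcomb)
```

## The problem

Human threat (fear) conditioning is usually quantified by conditioned
autonomic responses: skin conductance responses (SCR), pupil size responses
(PSR), heart period responses (HPR) and respiration amplitude responses
(RAR). Each participant contributes a CS+ minus CS− difference score per
measure, averaged over acquisition. Two questions drive this package. First,
do these four readouts vary along a single latent dimension between
participants, or several? Second, how much sharper does the inference
"conditioning occurred" become when the measures are combined linearly
instead of analyzed one at a time?

The sensitivity metric throughout is the one-sample Cohen's *d* of the
difference scores against zero — the measure's retrodictive validity.

## Scaling and screening

Different measurement chains report responses in arbitrary units, and units
differ between experiments. `scale_by_dataset_sd()` removes this nuisance
scale by dividing each participant's difference score by the sample SD
(denominator *n* − 1) of that measure *within its own dataset*, computed over
the complete cases entering the analysis at hand. Cohen's *d* itself is
scale-free, so scaling matters only when participants from several datasets
are pooled — which is exactly the pooled ("mega-analytic") setting the
package targets. Two readings of "the dataset's SD" are defensible: over the
complete-case subset being analyzed (default, `sd_scope = "subset"`) or over
all non-missing values of the measure in the dataset
(`sd_scope = "dataset"`). Both are exposed because the choice is not
determined by the pooled-analysis logic; the default keeps every analysis
self-contained.

Raw RAR differences are negative under successful conditioning (respiration
amplitude decreases in anticipation of the aversive outcome), while SCR, PSR
and HPR differences are positive. `effect_signs()` records these expected
directions and, with `orient = TRUE` (default), each column is flipped so the
expected effect is positive before any effect-size or weight computation.
Orientation changes only signs, never magnitudes: effect sizes and the
combined *d* are invariant, weight signs are not, so reports record whether
orientation was applied.

Screening (`screen_participants()`) flags difference scores lying more than a
per-measure threshold away from the cross-dataset mean, in cross-dataset SD
units: 3 SD for SCR, PSR and RAR, 5 SD for HPR, whose millisecond-scale
values have heavier technical tails. The default drops the whole participant
(a flagged value usually indicates a broken recording, not one broken
number); a value-level variant only blanks the offending entry. A whole
measure can also be excluded for a whole dataset, the remedy when one
experiment's recording chain was systematically faulty.

## The optimal combination

For weights $\mathbf{w}$ and measurement vector $\mathbf{x}_i$, the combined
score is $\mathbf{w}^\mathsf{T}\mathbf{x}_i$ with effect size

$$d(\mathbf{w}) \;=\; \frac{\mathbf{w}^\mathsf{T}\mathbf{m}}
{\sqrt{\mathbf{w}^\mathsf{T}\Sigma\,\mathbf{w}}},$$

where $\mathbf{m}$ is the sample mean vector and $\Sigma$ the
($n-1$-denominator) sample covariance. Maximizing $d^2$ is the Fisher
discriminant problem of separating the data cloud from the origin, with the
closed-form solution $\mathbf{w}^* \propto \Sigma^{-1}\mathbf{m}$
(`optimal_weights()`). Weights are reported at unit 2-norm; since
$d(-\mathbf{w}) = -d(\mathbf{w})$, the sign is fixed by
$\mathbf{w}^\mathsf{T}\mathbf{m} \ge 0$ so that reported weights always point
toward the conditioned effect. A singular $\Sigma$ (collinear columns) is
handled by the Moore–Penrose pseudo-inverse with a warning rather than by
ridge regularization: this leaves the estimator untouched whenever $\Sigma$
is invertible and degrades predictably on degenerate toy inputs. No
small-sample (Hedges) correction is applied to *d* anywhere. In-sample, the
optimal combined *d* can never fall below the best single measure's *d* (the
one-hot vector is a feasible direction), so in-sample gains are nonnegative
by construction and should be read as upper bounds.

## Dimensionality

`fit_factors()` extracts unrotated common factors from the correlation
matrix by minimum residual (unweighted least squares on the off-diagonal
correlations): uniquenesses are optimized (PORT/`nlminb`, bounded to
$[10^{-3}, 1]$, with a bounded quasi-Newton fallback when the objective is
nearly flat), and given uniquenesses the loadings are the leading
eigenvectors of the reduced correlation matrix. Reported uniquenesses are
$1 - $ communality, clamped at zero with a warning in Heywood cases. On
independent data the off-diagonal least-squares criterion can legitimately
park all communality on one variable (reproducing that variable's
correlation row exactly), so near-null solutions should be judged by the
implied common correlations $\Lambda\Lambda^\mathsf{T}$, not by raw loadings
— the test suite does exactly that.

`parallel_analysis()` decides the number of factors: observed eigenvalues
are compared component-wise against their Monte-Carlo distribution in
randomized data, and a component is retained while its empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{sim}} + 1)$ stays at or
below $\alpha$ (default 0.05), stopping at the first failure. Defaults,
each with an alternative behind a flag:

* **Eigenvalue family** — reduced correlation matrix with
  squared-multiple-correlation communalities on the diagonal (the
  common-factor variant), because the retention question is about common
  factors; `eigen_type = "pca"` uses the plain correlation matrix, matching
  tools whose defaults operate on principal-component eigenvalues. With 3–4
  measures the retained counts rarely differ.
* **Null generation** — independent column-wise permutations of the observed
  data, which destroy association while preserving each measure's margins
  and make no distributional assumption; `null_method = "gaussian"` draws
  standard-normal matrices instead.
* The $+1/+1$ correction keeps empirical p-values strictly positive, and
  `n_sim = 5000` is the production default (tests use 300–2000).

## Out-of-sample validation

In-sample gains are biased upward because the weights are tuned on the data
that evaluates them. `repeated_kfold_oos()` therefore runs repeated
(default 1000×) 5-fold cross-validation: per fold, weights and the identity
of the best single measure are determined on the training rows only, and
both the combined score and that single measure are scored by Cohen's *d* on
the held-out rows. Fold values are averaged within and then across
repetitions; since every fold contributes one combined and one best-single
value, averaging per-fold gains and differencing the two fold-averages
coincide whenever no fold is degenerate. Fold assignment is stratified by
dataset by default (`stratify_by_dataset`), so no fold is dominated by one
experiment; the unstratified variant matches a fully pseudo-random split.
Scaling is computed once on the full matrix before cross-validation,
mirroring a pipeline in which standardization precedes validation; this
leaks only the per-dataset SDs, to which Cohen's *d* is invariant within a
dataset.

Repetitions reuse the same participants, so the spread of per-repetition
gains understates the sampling variability of the estimate.
`bias_corrected_ci()` corrects this with a nested cross-validation pass: for
each outer fold, an inner $(k-1)$-fold cross-validation inside the training
set produces an internal estimate of the gain, and the squared discrepancy
between that inner estimate and the outer fold's realized gain accumulates
an estimate of the mean squared error of the cross-validated gain. Because
our cross-validated statistic is fold-level (a Cohen's-*d* gain, not a
per-observation loss), two noise terms are subtracted from the raw squared
discrepancies: the fold-level noise of the outer gain (pooled
within-repetition variance across folds) and the Monte-Carlo variance of the
inner mean itself, which with only $k-1$ fold-level values is far from
negligible. The interval half-width is the larger of the normal half-width
from this MSE estimate and the naive percentile half-width of the
per-repetition gains — the correction can only widen, never narrow, the
naive interval. The point estimate is shifted by $(1 + (k-2)/k)$ times the
inner/outer mean discrepancy, compensating the smaller training sets of the
inner pass. Intervals are reported at 90% (5% and 95% bounds) by default.

## Power planning

`required_n()` returns the smallest integer $N \ge 2$ whose *exact*
noncentral-t power (noncentrality $d\sqrt{N}$, $N-1$ degrees of freedom)
reaches the target for a two-tailed one-sample t-test — no normal
approximation; the large-sample formula only brackets the search.
`sample_size_reduction()` composes two such computations into the headline
percentage saving. Defaults (power 0.80, $\alpha$ 0.05, two-tailed) match
the standard planning scenario. Under these conventions the printed
effect-size pair 0.58/0.66 yields $N = 26$ and $N = 21$ (a 19% saving); a
normal-approximation computation would yield 24/19. Published sample-size
pairs computed with other conventions, or averaged over scenario tables,
need not coincide with the exact minimal-N definition used here.

## The synthetic generator

`generate_study()` draws difference scores from a linear common-factor
model: oriented score $y_{ij} = \mu_j + s_{dj} + \sum_k \lambda_{kj} f_{ik}
+ \varepsilon_{ij}$ with standard-normal factor scores, Gaussian noise, and
raw score $x_{ij} = \text{sign}_j \cdot c_{dj} \cdot y_{ij}$. Gaussianity is
a modeling choice (no distribution is implied by the pooled-analysis
setting): it makes the population effect sizes $d_j = \mu_j / \tau_j$, the
covariance $\Lambda^\mathsf{T}\Lambda + \text{diag}(\psi)$, the optimal
weights $\Sigma^{-1}\mathbf{m}$ and the optimal combined effect
$\sqrt{\mathbf{m}^\mathsf{T}\Sigma^{-1}\mathbf{m}}$ analytic, so parameter
recovery can be tested against closed forms (`synthetic_truth()`,
`analytic_combined_d()`). Per-dataset scale factors $c_{dj}$ emulate
measurement-system differences that the scaling stage must remove;
per-dataset mean shifts $s_{dj}$ emulate systematic between-experiment
variation in conditioning strength. One root seed drives per-dataset streams
derived by hashing the dataset label, so adding or removing a dataset leaves
the others' draws untouched.

Two presets encode the study conditions. `table1_preset()` reproduces the
nine-dataset layout: sample sizes 20, 26, 68, 22, 17, 12, 8, 19, 17 (209
complete participants), the published availability pattern (two datasets
with only SCR+PSR, three lacking PSR, one lacking RAR, three complete), one
latent factor with loadings SCR 0.59, PSR 0.73, RAR 0.10, HPR 0.41, unit
total variance, and per-dataset mean shifts calibrated so each dataset's
population effect sizes equal the published per-dataset values. The raw-unit
scales (SCR ≈ 0.2 µS, PSR ≈ 0.15 mm, HPR ≈ tens of ms) are chosen once as
realistic measurement-unit magnitudes. `fer02_preset()` is the
single-dataset analogue of the largest complete dataset (loadings 0.61,
0.67, 0.07, 0.34; effects 0.40, 0.52, 0.28, 0.26), whose implied optimal
combined effect is
$\sqrt{\mathbf{m}^\mathsf{T}\Sigma^{-1}\mathbf{m}} \approx 0.62$.

What the generator does *not* emulate: non-Gaussian tails and artifact
structure of real psychophysiology, trial-by-trial learning trajectories,
correlated observation noise between channels (e.g. respiratory influences
on heart period), and missingness mechanisms beyond dataset-level
availability. Passing tests therefore demonstrate that the statistical
machinery is correct and well-calibrated under the stated model, not that
real recordings satisfy the model.

## Numerical choices and test-scale conventions

Covariances use denominator $n-1$ throughout. Complete-case analysis only;
no imputation. Datasets contributing fewer than two complete cases to a
subset are dropped from that subset with a warning; a zero within-dataset SD
is an error. Degenerate cross-validation folds (zero score variance) are
skipped and counted. Weight normalization tolerance is $10^{-10}$;
optimality in tests is checked against $10^4$ random unit directions and a
refined hyperspherical grid to $10^{-3}$.

The test suite runs reduced problem sizes chosen to keep the full suite in a
few minutes while leaving Monte-Carlo error well below the asserted margins:
parallel-analysis replicates use `n_sim = 500` (production 5000),
cross-validation coverage checks use 200 repetitions (production 1000) over
100 replicates, and population-recovery checks use $n = 10^4$ with
3-standard-error tolerances.

## Limitations

The combination rule is linear and unregularized by design; with four
measures and pooled samples near a hundred participants this is the
appropriate complexity, but the closed form will overfit if transplanted to
many-measure settings. The factor analysis addresses between-person
covariance of acquisition-averaged scores only. The bias-corrected interval
is an adaptation of a per-observation-loss algorithm to fold-level
statistics; its coverage is validated by simulation in the test suite rather
than by theory.
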