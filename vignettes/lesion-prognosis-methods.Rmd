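---
title: "Predicting speech production after stroke from lesion images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting speech production after stroke from lesion images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

After a stroke, patients and clinicians want to know how severe a cognitive
impairment will be and how it is likely to evolve. `lesionprog` implements a
lesion-to-prognosis pipeline for one well-characterised outcome — a composite
speech-production T-score — built on the idea that symptoms and their
recovery depend on *which* brain regions were damaged, *how much* of each was
damaged, and *how long ago* the stroke occurred.

The pipeline has four stages:

1. **Lesion maps.** An upstream lesion-identification step (outside this
   package's scope) produces, per patient, a 3-D *abnormality image* in
   standard space (2 mm isotropic), each voxel coding tissue abnormality on a
   0–1 scale. `binarize_lesion()` thresholds it (strictly above 0.3) and
   removes connected components smaller than 100 voxels, leaving focal
   lesions only. Volume, left/right lateralised volumes and cohort overlap
   maps come from the binary mask.
2. **Atlas encoding.** `atlas_proportions()` projects the mask onto a
   parcellation: one damage proportion in [0, 1] per region — a compact,
   interpretable dimensionality reduction of the lesion.
3. **Regression.** `gp_fit()` learns the mapping from predictors
   (demographics, time post-stroke, lesion features) to the composite score
   with exact Gaussian-process regression, so each prediction is a Gaussian
   distribution: a point forecast *and* its confidence.
4. **Validation and prognosis.** Leave-one-out cross-validation
   (`loocv_cross_sectional()`), longitudinal evaluation on repeat visits
   (`longitudinal_eval()`), ARD-driven predictor selection (`rank_by_ard()`,
   `subset_search()`), and per-patient recovery curves over months
   post-stroke (`prognosis_curve()`).

## The outcome score

The Comprehensive Aphasia Test supplies per-task T-scores (lower = more
impaired, relative to an aphasic norming population). No single task isolates
speech production, so the composite takes four tasks — word and sentence
repetition (aural stimuli), object naming and picture description (visual
stimuli) — aligns each task's impairment threshold to a common reference
(60 by default; alignment adds `reference - threshold` to each task's
scores), then averages the *minimum* aligned score within the visual pair and
the minimum within the aural pair:

$$\mathrm{speech} = \tfrac12\left[\min(\text{naming},
\text{picture desc.}) + \min(\text{word rep.}, \text{sentence
rep.})\right]$$

Taking minima within each stimulus modality tracks impairment that cuts
across modalities rather than task-specific failures. On the aligned scale a
score below 60 falls in the bottom 5% of neurologically normal controls,
which is also the impairment cut-off used for ROC analyses. Per-task
thresholds are inputs (they derive from control norms this package does not
own); the composite is exactly invariant to shifting any task's scores and
threshold together, which the test suite asserts.

Cohort filters (`apply_selection_criteria()`) drop records with age at
stroke strictly below 20 or above 90 years, assessments earlier than 1 month
post-stroke, human-judged exclusion flags (other neurological conditions,
non-native language, no visible damage), and patients whose lesions vanish
under the 100-voxel cluster rule. Boundary ages 20 and 90 are retained.

## The Gaussian-process model

The regression model is $y = f(x) + \varepsilon(x)$ with a
rational-quadratic ARD covariance

$$k(x, x') = \sigma_f^2\left(1 + \frac{1}{2\alpha}\sum_d
\frac{(x_d - x'_d)^2}{\ell_d^2}\right)^{-\alpha},$$

Gaussian noise $\sigma_n^2$, and a Gaussian predictive distribution per
query: mean $k_*^\top (K + \sigma_n^2 I)^{-1} y$, variance
$\sigma_f^2 - k_*^\top (K + \sigma_n^2 I)^{-1} k_* + \sigma_n^2$. The
rational quadratic is a scale mixture of squared-exponential kernels, a
forgiving default when the characteristic scale of the lesion–behaviour
relationship is itself uncertain; as $\alpha \to \infty$ it collapses to the
squared exponential. One length scale $\ell_d$ per predictor gives automatic
relevance determination (ARD): maximizing the evidence pushes $\ell_d \to
\infty$ for predictors the data do not need, so $1/\ell_d$ (on the
standardized feature scale) ranks predictor relevance.

Hyperparameters are learned by maximizing the log marginal likelihood over
log-hyperparameters with scaled conjugate gradients (Møller's algorithm:
conjugate directions with a trust-region scaling in place of a line search;
an L-BFGS fallback sits behind `gp_control(optimizer = "lbfgs")`). The
evidence and its analytic gradient are computed in compiled code; the test
suite checks the gradient against central finite differences and the
predictive equations against a dense `solve()`-based oracle.

Numerical choices:

* Features are z-scored and the target centered *per training fold*
  (constant features get SD 1). This conditions the optimizer and prevents
  leakage of held-out statistics; predictions return to the original scale.
* Initialization: $\ell_d = 1$, $\sigma_f^2 = \mathrm{var}(y)$,
  $\sigma_n^2 = 0.1\,\mathrm{var}(y)$, $\alpha = 1$. Restarts jitter the
  log-hyperparameters with seeded Gaussian noise (SD 0.3) and the restart
  with the highest evidence wins. Full-data fits default to 2 restarts and
  150 iterations; the cross-validation helpers default to 1 restart and 60
  iterations, which on the synthetic cohorts loses under 0.01 of evidence-
  optimal R² per fold while keeping a 150-fold run in tens of seconds.
* If the covariance is numerically indefinite a diagonal jitter ladder
  (1e-10 to 1e-4, relative to $\sigma_f^2 + \sigma_n^2$) is climbed before
  giving up; non-finite covariances reject the hyperparameter step rather
  than crash the optimizer. If no restart improves on the initialization the
  initialization is returned with a warning — never a silent failure.

## Predictor configurations and selection

The configuration ladder mirrors progressively richer lesion information:
demographics only (`"dem"`: time post-stroke, age at stroke, gender,
handedness); plus total lesion volume (`"dem_lv"`); plus left/right
lateralised volumes (`"dem_latv"`); plus all per-region damage proportions
(`"atlas"`). ARD then ranks the atlas pool's predictors with one fit on the
whole dataset, and `subset_search()` re-runs the entire leave-one-out
validation on the top-$k$ predictors for growing $k$, reporting the smallest
size attaining the maximum R². Ranking once globally (rather than inside
each fold) is the filter design implemented here; it leaks ranking
information into the folds, so subset R² values are mildly optimistic — a
known property of filter feature selection that the package documents
rather than hides.

Validation metrics: R² from OLS of actual on predicted means (identical to
squared Pearson correlation in either direction; zero-variance predictions
give R² = 0 by convention), $F = (n-2)R^2/(1-R^2)$, error SD with the
$n-1$ denominator, paired Wilcoxon signed-rank Z on absolute errors
(tie-corrected normal approximation with continuity correction, zeros
dropped), and ROC AUC at the cut-off of 60 computed as rank-based pairwise
concordance with half credit for ties (identical to the threshold-sweep
area), with a seeded percentile-bootstrap CI (2000 resamples by default).

The longitudinal configuration fits once on all first visits and predicts
every repeat visit; each repeat patient's earlier scan, time and score are
deliberately in the training set, so the model extrapolates a known patient
forward in time. Prognosis curves (`prognosis_curve()`) hold a patient's
features fixed and sweep time post-stroke over months 1..250 (the default
horizon; configurable), after fitting without the target patient.

## The synthetic cohort generator

No suitable patient database is publicly deposited, so the package ships a
first-class generator (`simulate_cohort()`) with a fully known
structure–function–time model, used by every end-to-end test:

* **Geometry.** A toy ellipsoidal brain on a 40×48×40 grid of 2 mm voxels
  with the world origin at the grid center (x < 0 = left hemisphere), and a
  k-means (Voronoi) parcellation into 20 compact regions. Each patient gets
  one smooth ellipsoidal abnormality bump (peak 0.5–1, semi-axes 3.5–10
  voxels), placed left with probability 0.8, regenerated until it survives
  the 0.3/100-voxel binarization.
* **Impairment.** Three left-hemisphere regions are informative, with
  weights (35, 30, 25) T-score units per unit damage proportion, plus 20 T
  per unit lesioned brain fraction. Latent impairment is
  $I = \sum_r w_r d_r + w_V V/|brain|$, and the score at $t$ months is
  $\theta - I(\rho + (1-\rho)e^{-t/\tau}) + u + \varepsilon$ with ceiling
  $\theta = 70$, residual fraction $\rho = 0.5$, time constant $\tau = 6$
  months, a stable per-patient effect $u \sim N(0, 4^2)$ shared across a
  patient's visits, and record noise SD $\sigma = 3$. The
  saturating-exponential recovery is the simplest form with the right
  qualitative shape (steep early recovery, plateau); it is a test harness,
  not a scientific claim. The weights and residual fraction are calibrated
  so that full damage to key regions produces a severe, persistent deficit
  (~35 T below ceiling) and structural signal dominates noise — the regime
  a real aphasia cohort with scores spanning tens of T-points occupies. The
  patient effect represents individual factors (premorbid ability, therapy,
  education) that lesion anatomy cannot explain; it is what makes a
  patient's earlier assessment informative about their later one, and hence
  what gives the longitudinal configuration its advantage over the
  cross-sectional one — in real cohorts and in these simulations alike.
* **Behaviour.** The four task scores are the noisy latent score plus small
  seeded task offsets (SD 0.5), so the composite formula is genuinely
  exercised. Demographics (age 25–85, gender, handedness) are drawn
  independently of outcome, so demographics-only models should explain
  essentially nothing — the null the validation ladder starts from. Times
  post-stroke are log-normal (median 12 months, log-SD 0.8, clipped to
  [1, 240]); 15% of patients get one repeat visit 6–24 months later.

What the generator does *not* emulate: vascular-territory lesion shapes,
spatially correlated noise, multi-lesion patients, floor/ceiling compression
of real T-scores, and correlated demographics. Passing the synthetic
acceptance tests therefore demonstrates that the machinery recovers known
structure under clean conditions — not that real-cohort performance figures
transfer.

## Problem sizes and expected results

The end-to-end checks run at 150 patients, 20 regions, 3 informative,
σ = 3 (cross-sectional) and 100 patients with 30% repeat visits
(longitudinal) — sizes at which a full leave-one-out ladder completes in a
few minutes on one core. At these conditions the configuration ladder
reproduces, qualitatively, the ordering a real cohort shows: near-zero R²
for demographics, moderate for volume, higher with lateralisation, highest
with atlas features, with ARD selection recovering the informative regions
and matching or beating the full atlas pool. `scripts/acceptance.R`
recomputes exactly these quantities from scratch for any seed.

## Known limitations

* Exact GP inference is $O(n^3)$ per evidence evaluation; cohorts beyond a
  few thousand records would need inducing-point approximations, which are
  out of scope.
* The ARD ranking is a filter: correlated predictors share relevance
  unstably (a duplicated column halves both relevances), so the selected
  *set* is meaningful while individual ranks among correlated regions are
  not.
* Hemisphere assignment uses the world-x sign of voxel centers; voxels
  exactly on the midline plane belong to neither side.
* The Wilcoxon Z uses the normal approximation; for fewer than ~10 non-zero
  pairs exact enumeration (as in the test oracles) would be preferable.
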