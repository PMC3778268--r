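# lesionprog

Predicting the severity — and the likely time course — of post-stroke
speech-production impairment from structural lesion images.

`lesionprog` is an R implementation of a lesion-to-prognosis pipeline for
aphasia research: it converts per-patient 3-D tissue-abnormality images
(NIfTI, standard space, values 0–1) into binary lesion masks and atlas-based
regional damage features, combines those with demographics and time
post-stroke, and fits **Gaussian-process regression with a
rational-quadratic ARD covariance** to predict a composite speech-production
T-score. Because the GP returns a full Gaussian predictive distribution,
every forecast carries its own confidence, and sweeping the time-post-stroke
predictor turns the model into a per-patient **probabilistic recovery
prognosis** over months to decades.

## The model

Outcome: the composite speech score — after aligning the four task
thresholds to a common reference (60), the mean of the minimum aligned
T-score among visual-stimulus tasks (object naming, picture description) and
the minimum among aural-stimulus tasks (word and sentence repetition).
Scores below 60 are in the bottom 5% of neurologically normal controls.

Regression: `y = f(x) + ε(x)` with

```
k(x, x') = σ_f² (1 + (1/2α) Σ_d (x_d − x'_d)²/ℓ_d²)^(−α)
```

Gaussian noise σ_n², and hyperparameters learned by maximizing the log
marginal likelihood with scaled conjugate gradients. The per-predictor
length scales ℓ_d are the automatic-relevance-determination (ARD)
parameters: `1/ℓ_d` on the standardized feature scale ranks predictors, and
an incremental subset search over that ranking selects the best
configuration by leave-one-out cross-validated R².

## Worked example

No suitable patient cohort is publicly deposited, so the package ships a
synthetic-cohort generator with a fully known structure–function–time model
(lesions damage specific regions; damage causes impairment; impairment
partially recovers on a saturating-exponential curve). Everything below is
reproducible as written.

```r
library(lesionprog)

# 150 patients: toy brain, 20-region atlas, 3 informative regions, noise SD 3
cohort <- simulate_cohort(sim_config(n_patients = 150, seed = 7))
first  <- split_visits(cohort$records)$first

# configuration ladder, leave-one-out cross-validated
for (cf in c("dem", "dem_lv", "dem_latv", "atlas"))
  print(loocv_cross_sectional(first, cf, seed = 11))
#> Validation [dem]:      n = 150, R2 = 0.036, F = 5.48,   p = 0.0205, error SD = 8.71
#> Validation [dem_lv]:   n = 150, R2 = 0.024, F = 3.56,   p = 0.061, error SD = 8.92
#> Validation [dem_latv]: n = 150, R2 = 0.266, F = 53.73,  p = 1.39e-11, error SD = 7.59
#> Validation [atlas]:    n = 150, R2 = 0.564, F = 191.49, p = 1.8e-28, error SD = 5.84

# ARD ranks the 25 candidate predictors with one full-data fit
rk <- rank_by_ard(feature_matrix(first, "atlas"), first$speech_score, seed = 12)
head(rk$feature, 5)
#> [1] "dmg_region_05" "dmg_region_08" "dmg_region_13" "dmg_region_03"
#> [5] "dmg_region_01"
cohort$truth$informative_regions
#> [1] "region_05" "region_08" "region_13"

# incremental subset search over the ranking
ss <- subset_search(first, rk, size_min = 5, size_max = 25, step = 5, seed = 11)
ss$results
#>   size        r2 error_sd
#> 1    5 0.6472213 5.237472
#> 2   10 0.5857575 5.701538
#> 3   15 0.6196805 5.442221
#> 4   20 0.5852922 5.689697
#> 5   25 0.5639861 5.843697
```

Reading the output: demographics carry no real signal (the generator draws
them independently of outcome, so the first two rungs differ only by
cross-validation noise); lateralised volume and atlas-based damage features
then add large, genuine increments; and the ARD-selected 5-predictor subset
— whose top three predictors are exactly the three truly informative
regions — beats the full 25-predictor pool (R² 0.65 vs 0.56) because
irrelevant predictors only add variance. Error SD is in T-score units. A
per-patient prognosis is then one call:

```r
target <- first[1, ]
train  <- first[-1, ]   # leave the test patient out
model  <- gp_fit(feature_matrix(train, "atlas"), train$speech_score, seed = 1)
curve  <- prognosis_curve(model, unlist(target[feature_columns(first, "atlas")]),
                          t_max = 250)
plot(curve, observed = target)   # mean, ±2 SD band, threshold at 60
```

A thin CLI over the same functions lives at `inst/cli/lesionprog`
(`binarize`, `overlap`, `encode`, `score`, `simulate`, `crossval`,
`prognose`).

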