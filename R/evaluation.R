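#' Linear regression of actual on predicted scores
#'
#' The headline validation metric: ordinary least squares of the actual
#' scores on the predicted means. R-squared is the squared Pearson
#' correlation (identical in either regression direction),
#' `F = (n - 2) R^2 / (1 - R^2)` on (1, n - 2) degrees of freedom, with its
#' upper-tail p-value. Predictions with zero variance yield `R^2 = 0`,
#' `F = 0`, `p = 1` by convention.
#'
#' @param actual,predicted Equal-length numeric vectors (n >= 3).
#' @return List with `r2`, `f_stat`, `p_value`, `n`.
#' @export
regress_actual_on_predicted <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 3)
  n <- length(actual)
  if (sd(predicted) < 1e-12 || sd(actual) < 1e-12)
    return(list(r2 = 0, f_stat = 0, p_value = 1, n = n))
  fit <- lm(actual ~ predicted)
  # summary.lm warns on exact fits; R2 = 1 is a legitimate outcome here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  f_stat <- (n - 2) * r2 / (1 - r2)
  list(r2 = r2, f_stat = f_stat,
       p_value = pf(f_stat, 1, n - 2, lower.tail = FALSE), n = n)
}

#' Standard deviation of prediction errors
#'
#' SD (denominator n - 1) of `actual - predicted`; the width of the error
#' distribution, in target (T-score) units.
#'
#' @inheritParams regress_actual_on_predicted
#' @return Numeric scalar.
#' @export
error_sd <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  sd(actual - predicted)
}

#' Paired Wilcoxon signed-rank comparison of absolute errors
#'
#' Tests whether one configuration's absolute prediction errors tend to be
#' larger than another's on the same patients: a Wilcoxon signed-rank test
#' on the paired differences `abs_errors_a - abs_errors_b`, with zero
#' differences dropped, tie-corrected normal approximation and continuity
#' correction. Positive Z means configuration a errs more than b.
#'
#' @param abs_errors_a,abs_errors_b Paired absolute-error vectors.
#' @return List with `z`, `p_value` (two-sided), `statistic` (signed-rank
#'   sum W+), `n` (non-zero pairs).
#' @export
compare_errors_wilcoxon <- function(abs_errors_a, abs_errors_b) {
  stopifnot(length(abs_errors_a) == length(abs_errors_b))
  d <- abs_errors_a - abs_errors_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(z = 0, p_value = 1, statistic = 0, n = 0L))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(list(z = 0, p_value = 1, statistic = w_plus, n = n))
  cc <- 0.5 * sign(w_plus - mu)
  z <- (w_plus - mu - cc) / sqrt(sigma2)
  list(z = z, p_value = 2 * pnorm(-abs(z)), statistic = w_plus, n = n)
}

#' ROC area under the curve for impairment classification
#'
#' Labels each record impaired when its *actual* score falls below
#' `cutoff` (default 60, the control-derived impairment threshold), then
#' treats the predicted means as a continuous decision score swept over all
#' thresholds. The AUC is computed as pairwise concordance -- the
#' probability that a randomly chosen impaired record has a lower predicted
#' score than a randomly chosen unimpaired one, with half credit for ties
#' -- which is exactly the threshold-sweep (trapezoidal) ROC area. The
#' confidence interval is a seeded percentile bootstrap over records.
#'
#' @param predicted Predicted mean scores.
#' @param actual Actual scores, used only for labelling.
#' @param cutoff Impairment threshold on the actual scores. Default 60.
#' @param n_boot Bootstrap resamples for the CI. Default 2000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Seed for the bootstrap.
#' @return List of class `roc_result`: `auc`, `ci` (lower, upper), `cutoff`,
#'   `n_impaired`, `n_unimpaired`.
#' @export
roc_auc <- function(predicted, actual, cutoff = 60, n_boot = 2000,
                    conf = 0.95, seed = NULL) {
  stopifnot(length(predicted) == length(actual))
  impaired <- actual < cutoff
  if (!any(impaired) || all(impaired))
    stop("both impaired and unimpaired records are required at cutoff ",
         cutoff)
  auc <- concordance_auc(predicted, impaired)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- length(predicted)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        lab <- impaired[idx]
        if (!any(lab) || all(lab)) return(NA_real_)
        concordance_auc(predicted[idx], lab)
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    a <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(a, 1 - a), type = 7))
  }
  structure(list(auc = auc, ci = ci, cutoff = cutoff,
                 n_impaired = sum(impaired),
                 n_unimpaired = sum(!impaired)),
            class = "roc_result")
}

# P(score_impaired < score_unimpaired) + 0.5 P(tie), via midranks:
# identical to sweeping a decision threshold over the scores.
concordance_auc <- function(score, impaired) {
  r <- rank(score)
  n1 <- sum(impaired)
  n0 <- sum(!impaired)
  (sum(r[!impaired]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), cutoff %g, %d impaired / %d unimpaired\n",
              x$auc, x$ci[1], x$ci[2], x$cutoff, x$n_impaired, x$n_unimpaired))
  invisible(x)
}

new_validation_result <- function(predictions, config, n_skipped = 0L) {
  ok <- is.finite(predictions$predicted_mean)
  metrics <- if (sum(ok) >= 3)
    regress_actual_on_predicted(predictions$actual[ok],
                                predictions$predicted_mean[ok])
  else list(r2 = NA_real_, f_stat = NA_real_, p_value = NA_real_)
  structure(list(predictions = predictions,
                 r2 = metrics$r2, f_stat = metrics$f_stat,
                 p_value = metrics$p_value,
                 error_sd = if (sum(ok) >= 2)
                   error_sd(predictions$actual[ok],
                            predictions$predicted_mean[ok]) else NA_real_,
                 config = config, n = sum(ok), n_skipped = n_skipped),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Validation [%s]: n = %d, R2 = %.3f, F = %.2f, p = %.3g, error SD = %.2f\n",
              x$config, x$n, x$r2, x$f_stat, x$p_value, x$error_sd))
  if (x$n_skipped > 0) cat(" ", x$n_skipped, "fold(s) skipped\n")
  invisible(x)
}

#' Leave-one-out cross-sectional validation
#'
#' One fold per patient: the model is fitted on every other patient's first
#' assessment and predicts the held-out patient's composite speech score.
#' Standardization and hyperparameter learning happen inside each fold, so
#' no held-out information reaches the learner. A fold whose fit fails is
#' recorded and skipped with a warning.
#'
#' @param records Patient table with one row per patient (first visits
#'   only); must contain `speech_score` and the configuration's feature
#'   columns.
#' @param config Predictor configuration (see [feature_columns()]).
#' @param control A [gp_control()]; the default uses a single optimizer
#'   start per fold.
#' @param seed Integer seed; per-fold restart seeds are derived from it.
#' @param folds Optional integer vector of record indices to evaluate
#'   (default: all). Fitting always uses all other records.
#' @return A `validation_result`: per-fold predictions (`patient_id`,
#'   `actual`, `predicted_mean`, `predicted_variance`), `r2`, `f_stat`,
#'   `p_value`, `error_sd`.
#' @export
loocv_cross_sectional <- function(records, config = "atlas",
                                  control = gp_control(restarts = 1, maxit = 60),
                                  seed = NULL, folds = NULL) {
  records <- as.data.frame(records)
  if ("visit_index" %in% names(records) && any(records$visit_index != 1L))
    stop("cross-sectional validation expects first visits only")
  if (anyDuplicated(records$patient_id))
    stop("one record per patient required")
  n <- nrow(records)
  folds <- folds %||% seq_len(n)
  X <- feature_matrix(records, config)
  y <- records$speech_score
  seeds <- child_seeds(seed %||% 0L, n)
  pred_mean <- rep(NA_real_, length(folds))
  pred_var <- rep(NA_real_, length(folds))
  n_skipped <- 0L
  for (j in seq_along(folds)) {
    i <- folds[j]
    fit <- tryCatch(
      gp_fit(X[-i, , drop = FALSE], y[-i], control = control,
             seed = seeds[i]),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fold ", i, " skipped: ", conditionMessage(fit))
      n_skipped <- n_skipped + 1L
      next
    }
    p <- predict(fit, X[i, , drop = FALSE])
    pred_mean[j] <- p$mean
    pred_var[j] <- p$variance
  }
  predictions <- data.frame(patient_id = records$patient_id[folds],
                            actual = y[folds],
                            predicted_mean = pred_mean,
                            predicted_variance = pred_var,
                            stringsAsFactors = FALSE)
  new_validation_result(predictions, config_label(config), n_skipped)
}

#' Longitudinal validation on repeat visits
#'
#' A single model is fitted on all first-visit records; it then predicts the
#' composite score at every repeat visit. Each repeat-visit patient's
#' earlier scan, time post-stroke and score are part of the training set --
#' the longitudinal configuration -- so the model is extrapolating a known
#' patient forward in time rather than generalizing to an unseen one.
#' Repeat records for patients absent from training are still predicted but
#' flagged.
#'
#' @param first_visits Patient table of first assessments (training).
#' @param repeat_visits Patient table of later assessments to predict.
#' @param config Predictor configuration (see [feature_columns()]).
#' @param control A [gp_control()].
#' @param seed Integer seed for the fit.
#' @return A `validation_result` whose `predictions` carry an extra
#'   `in_training` flag; empty `repeat_visits` yield an empty result.
#' @export
longitudinal_eval <- function(first_visits, repeat_visits, config = "atlas",
                              control = gp_control(restarts = 1, maxit = 60),
                              seed = NULL) {
  first_visits <- as.data.frame(first_visits)
  repeat_visits <- as.data.frame(repeat_visits)
  if (nrow(repeat_visits) == 0) {
    predictions <- data.frame(patient_id = character(), actual = numeric(),
                              predicted_mean = numeric(),
                              predicted_variance = numeric(),
                              in_training = logical(),
                              stringsAsFactors = FALSE)
    return(structure(list(predictions = predictions, r2 = NA_real_,
                          f_stat = NA_real_, p_value = NA_real_,
                          error_sd = NA_real_,
                          config = config_label(config), n = 0L,
                          n_skipped = 0L),
                     class = "validation_result"))
  }
  model <- gp_fit(feature_matrix(first_visits, config),
                  first_visits$speech_score, control = control, seed = seed)
  known <- repeat_visits$patient_id %in% first_visits$patient_id
  if (any(!known))
    warning(sum(!known), " repeat record(s) belong to patients absent from training")
  p <- predict(model, feature_matrix(repeat_visits, config))
  predictions <- data.frame(patient_id = repeat_visits$patient_id,
                            actual = repeat_visits$speech_score,
                            predicted_mean = p$mean,
                            predicted_variance = p$variance,
                            in_training = known,
                            stringsAsFactors = FALSE)
  res <- new_validation_result(predictions, config_label(config))
  res$model <- model
  res
}
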