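#' Probabilistic recovery prognosis over time
#'
#' Produces a per-patient prognosis curve: the model's Gaussian predictive
#' distribution of the composite speech score at each month post-stroke,
#' obtained by holding every feature at the patient's values and replacing
#' time post-stroke with 1, 2, ... up to `t_max` months. For a leave-one-out
#' prognosis, fit the model without the target patient first. The band is
#' mean +/- 2 predictive SDs (~95%).
#'
#' @param model A fitted `gp_model` whose features include the time column.
#' @param patient_features Named numeric vector (or one-row data frame) with
#'   the model's feature columns, including the patient's own
#'   `time_post_stroke` value (which the sweep replaces).
#' @param t_max Last month to predict. Default 250.
#' @param time_feature Name of the time column. Default `"time_post_stroke"`.
#' @return Data frame of class `prognosis_curve` with columns `month`,
#'   `mean`, `variance`, `sd`, `lower`, `upper` (mean -/+ 2 SD), one row per
#'   month 1..`t_max`.
#' @export
prognosis_curve <- function(model, patient_features, t_max = 250,
                            time_feature = "time_post_stroke") {
  stopifnot(inherits(model, "gp_model"))
  if (t_max < 1) stop("`t_max` must be at least 1")
  if (is.data.frame(patient_features))
    patient_features <- unlist(patient_features[1, , drop = TRUE])
  feats <- model$feature_names %||% names(patient_features)
  if (!all(feats %in% names(patient_features)))
    stop("patient_features is missing model feature(s): ",
         paste(setdiff(feats, names(patient_features)), collapse = ", "))
  if (!time_feature %in% feats)
    stop("model has no feature named ", time_feature)
  months <- seq_len(t_max)
  X <- matrix(rep(patient_features[feats], each = t_max), nrow = t_max,
              dimnames = list(NULL, feats))
  X[, time_feature] <- months
  p <- predict(model, X)
  structure(data.frame(month = months, mean = p$mean,
                       variance = p$variance, sd = p$sd,
                       lower = p$mean - 2 * p$sd,
                       upper = p$mean + 2 * p$sd),
            class = c("prognosis_curve", "data.frame"))
}

#' Plot a prognosis curve
#'
#' Mean prediction with the +/- 2 SD band, the impairment threshold as a
#' dashed reference, and optionally the patient's observed assessments.
#'
#' @param x A [prognosis_curve()].
#' @param observed Optional data frame with columns `time_post_stroke` and
#'   `speech_score` of actual assessments to overlay.
#' @param threshold Reference impairment threshold. Default 60.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.prognosis_curve <- function(x, observed = NULL, threshold = 60, ...) {
  ylim <- range(x$lower, x$upper, threshold,
                if (!is.null(observed)) observed$speech_score)
  graphics::plot(x$month, x$mean, type = "n", ylim = ylim,
                 xlab = "Months post-stroke",
                 ylab = "Speech production score (T)", ...)
  graphics::polygon(c(x$month, rev(x$month)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(x$month, x$mean, lwd = 2)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  if (!is.null(observed))
    graphics::points(observed$time_post_stroke, observed$speech_score,
                     pch = 19, col = "firebrick")
  invisible(x)
}

#' Write a prognosis curve to CSV
#'
#' @param x A [prognosis_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prognosis_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("month", "mean", "sd", "lower", "upper")],
                   path, row.names = FALSE)
  invisible(path)
}
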