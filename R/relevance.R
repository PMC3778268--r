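#' Rank predictors by ARD relevance
#'
#' A Bayesian filter pass: one GP model is fitted on the *whole* dataset
#' with an individual (ARD) length scale per predictor, and each predictor's
#' relevance is the inverse of its learned length scale on the standardized
#' feature scale -- a short length scale means the evidence wanted the
#' function to vary along that predictor. Ranking once globally (rather than
#' within each cross-validation fold) leaks some ranking information into
#' later validation folds; this is a deliberate property of the filter
#' design, and subset R-squared values should be read accordingly.
#'
#' @param X Feature matrix (columns = candidate predictors; typically the
#'   richest configuration, `feature_matrix(records, "atlas")`).
#' @param y Target vector.
#' @param seed Integer seed for the fit's restarts.
#' @param control A [gp_control()].
#' @return Data frame of class `relevance_ranking` with columns `feature`,
#'   `relevance` (1 / length scale), `length_scale`, sorted by descending
#'   relevance; ties broken by original column index (stable).
#' @export
rank_by_ard <- function(X, y, seed = NULL, control = gp_control()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  model <- gp_fit(X, y, control = control, seed = seed)
  ell <- model$hyperparams$length_scales
  ord <- order(-(1 / ell), seq_along(ell))
  out <- data.frame(feature = colnames(X)[ord],
                    relevance = unname(1 / ell[ord]),
                    length_scale = unname(ell[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "model") <- model
  class(out) <- c("relevance_ranking", "data.frame")
  out
}

#' Incremental subset search over ARD-ranked predictors
#'
#' Grows the predictor configuration in relevance order -- the top
#' `size_min` predictors, then `size_min + step`, and so on up to
#' `size_max` -- re-running the full leave-one-out validation at each size
#' and recording the cross-validated R-squared. The best size is the
#' smallest one attaining the maximum R-squared.
#'
#' @param records Patient table (first visits only).
#' @param ranking A [rank_by_ard()] result covering the candidate pool.
#' @param size_min,size_max,step Subset-size grid (defaults 5, 65, 1). If
#'   `size_max` exceeds the number of ranked features it is truncated with a
#'   warning.
#' @param control A [gp_control()] passed to each fold's fit.
#' @param seed Integer seed shared by every leave-one-out run.
#' @return List of class `subset_search_result`: `results` (data frame
#'   `size`, `r2`, `error_sd`), `best_size`, `best_features`, `best` (the
#'   best size's `validation_result`).
#' @export
subset_search <- function(records, ranking, size_min = 5, size_max = 65,
                          step = 1, control = gp_control(restarts = 1, maxit = 60),
                          seed = NULL) {
  stopifnot(inherits(ranking, "relevance_ranking"))
  n_feat <- nrow(ranking)
  if (size_max > n_feat) {
    warning("size_max (", size_max, ") exceeds the ", n_feat,
            " ranked features; truncating")
    size_max <- n_feat
  }
  size_min <- min(size_min, size_max)
  sizes <- seq(size_min, size_max, by = step)
  runs <- vector("list", length(sizes))
  for (j in seq_along(sizes)) {
    feats <- ranking$feature[seq_len(sizes[j])]
    runs[[j]] <- loocv_cross_sectional(records, config = feats,
                                       control = control, seed = seed)
  }
  r2 <- vapply(runs, `[[`, numeric(1), "r2")
  best_j <- which.max(r2)          # first attainment wins ties
  structure(list(results = data.frame(
                   size = sizes, r2 = r2,
                   error_sd = vapply(runs, `[[`, numeric(1), "error_sd")),
                 best_size = sizes[best_j],
                 best_features = ranking$feature[seq_len(sizes[best_j])],
                 best = runs[[best_j]]),
            class = "subset_search_result")
}

#' @export
print.subset_search_result <- function(x, ...) {
  cat(sprintf("Subset search over sizes %d-%d: best size %d (R2 = %.3f)\n",
              min(x$results$size), max(x$results$size), x$best_size,
              max(x$results$r2)))
  invisible(x)
}

#' Plot cross-validated R-squared against subset size
#'
#' @param x A `subset_search_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.subset_search_result <- function(x, ...) {
  graphics::plot(x$results$size, x$results$r2, type = "b", pch = 16,
                 xlab = "Number of ARD-selected predictors",
                 ylab = expression(LOOCV ~ R^2), ...)
  graphics::abline(v = x$best_size, lty = 2, col = "grey40")
  invisible(x)
}
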