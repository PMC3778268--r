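#' Rational-quadratic ARD covariance function
#'
#' The kernel behind all models in this package:
#' \deqn{k(x, x') = \sigma_f^2 \left(1 + \frac{1}{2\alpha}\sum_d
#'   \frac{(x_d - x'_d)^2}{\ell_d^2}\right)^{-\alpha}}
#' a scale mixture of squared-exponential kernels over length scales, with
#' one length scale \eqn{\ell_d} per predictor (the ARD parameters: a large
#' learned \eqn{\ell_d} means predictor d is irrelevant). As
#' \eqn{\alpha \to \infty} it approaches the squared-exponential kernel.
#'
#' @param x1,x2 Numeric matrices (rows = points) or vectors (treated as
#'   single points) with the same number of columns.
#' @param signal_variance \eqn{\sigma_f^2 > 0}, the prior variance at zero
#'   distance.
#' @param alpha Shape \eqn{\alpha > 0} of the rational quadratic.
#' @param length_scales Positive vector \eqn{\ell_d}, recycled to the input
#'   dimension.
#' @return Matrix of covariances, `nrow(x1)` by `nrow(x2)`.
#' @export
rq_kernel <- function(x1, x2, signal_variance = 1, alpha = 1,
                      length_scales = 1) {
  if (!is.matrix(x1)) x1 <- matrix(x1, nrow = 1)
  if (!is.matrix(x2)) x2 <- matrix(x2, nrow = 1)
  if (ncol(x1) != ncol(x2)) stop("x1 and x2 must have the same dimension")
  if (signal_variance <= 0 || alpha <= 0 || any(length_scales <= 0))
    stop("kernel hyperparameters must be strictly positive")
  ell <- rep_len(length_scales, ncol(x1))
  rq_kernel_cpp(x1, x2, signal_variance, alpha, ell)
}

#' Control parameters for GP fitting
#'
#' @param maxit Maximum optimizer iterations per restart.
#' @param restarts Number of optimizer runs; the first starts from the
#'   default initialization, later ones jitter the log-hyperparameters with
#'   seeded Gaussian noise (SD `restart_sd`) and the run with the highest
#'   evidence wins.
#' @param restart_sd SD of the restart jitter on the log scale.
#' @param tol Gradient infinity-norm convergence tolerance.
#' @param jitter_max Largest relative diagonal jitter tried to make the
#'   covariance factorizable (ladder 1e-10 ... `jitter_max`).
#' @param optimizer `"scg"` (scaled conjugate gradients, default) or
#'   `"lbfgs"` (`stats::optim` L-BFGS-B fallback).
#' @return A list of class `gp_control`.
#' @export
gp_control <- function(maxit = 150, restarts = 2, restart_sd = 0.3,
                       tol = 1e-5, jitter_max = 1e-4,
                       optimizer = c("scg", "lbfgs")) {
  structure(list(maxit = maxit, restarts = restarts, restart_sd = restart_sd,
                 tol = tol, jitter_max = jitter_max,
                 optimizer = match.arg(optimizer)),
            class = "gp_control")
}

# negative log marginal likelihood + gradient at log-hyperparameters theta
gp_objective <- function(theta, X, y, jitter_max) {
  res <- gp_nlml_cpp(theta, X, y, TRUE, jitter_max)
  if (!isTRUE(res$ok)) return(list(f = Inf, g = rep(NA_real_, length(theta))))
  list(f = res$value, g = as.numeric(res$grad))
}

#' Fit a Gaussian-process regression model
#'
#' Exact GP regression `y = f(x) + e(x)` with the rational-quadratic ARD
#' covariance ([rq_kernel()]) and Gaussian noise, trained by maximizing the
#' log marginal likelihood (evidence) over log-hyperparameters with scaled
#' conjugate gradients. Features are z-scored and the target centered using
#' the *training data only* (constant features get SD 1), so no held-out
#' information leaks into prediction; predictions are returned on the
#' original target scale.
#'
#' Initialization: all length scales 1 (standardized units),
#' `signal_variance = var(y)`, `noise_variance = 0.1 var(y)`, `alpha = 1`.
#'
#' @param X Numeric feature matrix (or data frame), rows = patients.
#' @param y Numeric target vector (composite T-scores).
#' @param control A [gp_control()].
#' @param seed Integer seed driving the restart jitter; fits are
#'   deterministic given the seed.
#' @return An object of class `gp_model` with the fitted `hyperparams`
#'   (`signal_variance`, `noise_variance`, `alpha`, `length_scales`), the
#'   standardization stats, the cached Cholesky factorization and the
#'   maximized `evidence` (log marginal likelihood).
#' @export
gp_fit <- function(X, y, control = gp_control(), seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2) stop("need at least 2 training points")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd)
  x_scale[!is.finite(x_scale) | x_scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  yc <- y - y_center

  vy <- var(yc)
  if (!is.finite(vy) || vy < 1e-12) vy <- 1
  theta0 <- c(log(vy), log(0.1 * vy), 0, rep(0, d))

  n_restart <- max(1L, control$restarts)
  jit <- matrix(0, n_restart, length(theta0))
  if (n_restart > 1)
    jit[-1, ] <- with_seed(seed, matrix(
      rnorm((n_restart - 1) * length(theta0), 0, control$restart_sd),
      n_restart - 1))

  obj <- function(th) gp_objective(th, Xs, yc, control$jitter_max)
  best <- NULL
  f0 <- obj(theta0)$f
  for (r in seq_len(n_restart)) {
    th_init <- theta0 + jit[r, ]
    fit <- tryCatch({
      if (control$optimizer == "scg") {
        scg_minimize(th_init, obj, maxit = control$maxit, tol = control$tol)
      } else {
        o <- stats::optim(th_init, fn = function(t) obj(t)$f,
                          gr = function(t) obj(t)$g, method = "L-BFGS-B",
                          control = list(maxit = control$maxit))
        list(par = o$par, value = o$value, trace = NULL)
      }
    }, error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value > f0) {
    warning("optimizer failed to improve on the initialization; ",
            "returning initial hyperparameters")
    best <- list(par = theta0, value = f0, trace = f0)
  }

  theta <- best$par
  model <- structure(
    list(theta = theta,
         hyperparams = theta_to_hyperparams(theta, colnames(X)),
         X = Xs, y = yc,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         feature_names = colnames(X),
         evidence = -best$value, nlml_trace = best$trace,
         control = control, n = n, d = d),
    class = "gp_model")
  model <- cache_factorization(model)
  model
}

#' Construct a GP model at fixed hyperparameters
#'
#' Builds a ready-to-predict model without any optimization: useful for
#' studying the model at known hyperparameters (e.g. near-zero noise for
#' interpolation) and as the entry point for models whose hyperparameters
#' were selected elsewhere. Standardization can be disabled to work on the
#' raw feature/target scales.
#'
#' @inheritParams gp_fit
#' @param hyperparams List with `signal_variance`, `noise_variance`,
#'   `alpha`, `length_scales` (scalar length scales are recycled across
#'   features).
#' @param standardize Z-score features and center the target (default
#'   `TRUE`, matching [gp_fit()]).
#' @return A `gp_model`.
#' @export
gp_model <- function(X, y, hyperparams, control = gp_control(),
                     standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  d <- ncol(X)
  hyperparams$length_scales <- rep_len(hyperparams$length_scales, d)
  if (standardize) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, sd)
    x_scale[!is.finite(x_scale) | x_scale < 1e-12] <- 1
    y_center <- mean(y)
  } else {
    x_center <- rep(0, d)
    x_scale <- rep(1, d)
    y_center <- 0
  }
  theta <- hyperparams_to_theta(hyperparams)
  model <- structure(
    list(theta = theta,
         hyperparams = theta_to_hyperparams(theta, colnames(X)),
         X = sweep(sweep(X, 2, x_center), 2, x_scale, "/"),
         y = y - y_center,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         feature_names = colnames(X),
         evidence = NA_real_, nlml_trace = NULL,
         control = control, n = n, d = d),
    class = "gp_model")
  model <- cache_factorization(model)
  model$evidence <- gp_log_marginal(model)$value
  model
}

theta_to_hyperparams <- function(theta, feature_names = NULL) {
  d <- length(theta) - 3L
  ell <- exp(theta[seq_len(d) + 3L])
  if (!is.null(feature_names)) names(ell) <- feature_names
  list(signal_variance = exp(theta[1]), noise_variance = exp(theta[2]),
       alpha = exp(theta[3]), length_scales = ell)
}

hyperparams_to_theta <- function(h) {
  stopifnot(h$signal_variance > 0, h$noise_variance > 0, h$alpha > 0,
            all(h$length_scales > 0))
  c(log(h$signal_variance), log(h$noise_variance), log(h$alpha),
    log(h$length_scales))
}

# Cholesky of K + sn2 I with the jitter ladder; caches L and alpha = Ky^-1 y.
cache_factorization <- function(model) {
  h <- model$hyperparams
  K <- rq_kernel_cpp(model$X, model$X, h$signal_variance, h$alpha,
                     h$length_scales)
  Ky <- K + diag(h$noise_variance, model$n)
  scale <- h$signal_variance + h$noise_variance
  jitter_used <- 0
  L <- tryCatch(t(chol(Ky)), error = function(e) NULL)
  if (is.null(L)) {
    for (j in 10^seq(-10, log10(model$control$jitter_max))) {
      L <- tryCatch(t(chol(Ky + diag(j * scale, model$n))),
                    error = function(e) NULL)
      if (!is.null(L)) { jitter_used <- j * scale; break }
    }
  }
  if (is.null(L))
    stop("covariance not positive definite even after maximal jitter; ",
         "condition estimate ", format(kappa(Ky)))
  model$L <- L
  model$alpha_vec <- backsolve(t(L), forwardsolve(L, model$y))
  model$jitter <- jitter_used
  model
}

#' Log marginal likelihood of a GP model
#'
#' Evaluates the evidence
#' \eqn{-\tfrac12 y^T K_y^{-1} y - \tfrac12 \log|K_y| - \tfrac{n}{2}\log 2\pi}
#' (with \eqn{K_y = K + \sigma_n^2 I}) at the model's fitted
#' hyperparameters, or at supplied ones, together with its gradient with
#' respect to the log-hyperparameters.
#'
#' @param model A fitted `gp_model`.
#' @param hyperparams Optional list with `signal_variance`,
#'   `noise_variance`, `alpha`, `length_scales` at which to evaluate.
#' @return List with `value` (log marginal likelihood) and `gradient`
#'   (named: `log_signal_variance`, `log_noise_variance`, `log_alpha`, one
#'   `log_ell_*` per feature).
#' @export
gp_log_marginal <- function(model, hyperparams = NULL) {
  stopifnot(inherits(model, "gp_model"))
  theta <- if (is.null(hyperparams)) model$theta
    else hyperparams_to_theta(hyperparams)
  res <- gp_nlml_cpp(theta, model$X, model$y, TRUE,
                     model$control$jitter_max)
  if (!isTRUE(res$ok))
    stop("covariance not positive definite at the supplied hyperparameters")
  g <- -as.numeric(res$grad)
  names(g) <- c("log_signal_variance", "log_noise_variance", "log_alpha",
                paste0("log_ell_",
                       model$feature_names %||% seq_len(model$d)))
  list(value = -res$value, gradient = g)
}

#' Predict from a fitted GP model
#'
#' Returns the Gaussian predictive distribution for new observations:
#' mean \eqn{k_*^T K_y^{-1} y} (plus the training target mean) and variance
#' \eqn{\sigma_f^2 - k_*^T K_y^{-1} k_* + \sigma_n^2}. The noise variance is
#' included, so the distribution is for a new *measured* score, and the
#' variance is bounded by \eqn{\sigma_f^2 + \sigma_n^2} (prior reversion far
#' from the training data).
#'
#' @param object A fitted `gp_model`.
#' @param newdata Matrix or data frame of features with the training columns.
#' @param ... Unused.
#' @return Data frame with one row per query: `mean`, `variance`, `sd`.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$d)
    stop("newdata has ", ncol(X), " columns; model expects ", object$d)
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names))
    X <- X[, object$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  h <- object$hyperparams
  ks <- rq_kernel_cpp(Xs, object$X, h$signal_variance, h$alpha,
                      h$length_scales)
  mu <- as.numeric(ks %*% object$alpha_vec) + object$y_center
  v <- forwardsolve(object$L, t(ks))
  var_f <- h$signal_variance - colSums(v^2)
  variance <- pmax(var_f, 0) + h$noise_variance
  data.frame(mean = mu, variance = variance, sd = sqrt(variance))
}

#' @export
print.gp_model <- function(x, ...) {
  h <- x$hyperparams
  cat("Gaussian process regression (rational-quadratic ARD kernel)\n")
  cat(sprintf("  n = %d, d = %d, evidence = %.3f\n", x$n, x$d, x$evidence))
  cat(sprintf("  signal sd = %.3f, noise sd = %.3f, alpha = %.3f\n",
              sqrt(h$signal_variance), sqrt(h$noise_variance), h$alpha))
  ell <- sort(h$length_scales)
  k <- min(5, length(ell))
  cat("  shortest length scales:",
      paste(sprintf("%s=%.2f", names(ell)[seq_len(k)] %||% seq_len(k),
                    ell[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a GP model to JSON
#'
#' Writes hyperparameters, standardization stats, training data and a
#' training-data checksum to a plain-text JSON file; [gp_load()] restores a
#' working model (refactorizing the covariance) and verifies the checksum.
#'
#' @param model A fitted `gp_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
gp_save <- function(model, path) {
  stopifnot(inherits(model, "gp_model"))
  payload <- list(
    hyperparams = model$hyperparams,
    theta = model$theta,
    X = model$X, y = model$y,
    x_center = model$x_center, x_scale = model$x_scale,
    y_center = model$y_center,
    feature_names = model$feature_names,
    evidence = model$evidence,
    control = unclass(model$control))
  payload$checksum <- gp_checksum(model)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# 15 significant digits: stable across a JSON round trip (which renders
# doubles at that precision) while still catching any real data change.
gp_checksum <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(sprintf("%.14e", c(as.numeric(model$X), model$y)),
                   collapse = ","), f)
  unname(tools::md5sum(f))
}

#' @rdname gp_save
#' @export
gp_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(p$x_center)
  model <- structure(
    list(theta = as.numeric(p$theta),
         hyperparams = list(
           signal_variance = p$hyperparams$signal_variance,
           noise_variance = p$hyperparams$noise_variance,
           alpha = p$hyperparams$alpha,
           length_scales = setNames(
             as.numeric(unlist(p$hyperparams$length_scales)),
             p$feature_names)),
         X = matrix(as.numeric(as.matrix(p$X)), ncol = d),
         y = as.numeric(p$y),
         x_center = as.numeric(p$x_center), x_scale = as.numeric(p$x_scale),
         y_center = p$y_center,
         feature_names = p$feature_names,
         evidence = p$evidence,
         control = do.call(gp_control, p$control[setdiff(names(p$control), "optimizer")]),
         n = length(p$y), d = d),
    class = "gp_model")
  model <- cache_factorization(model)
  if (!identical(gp_checksum(model), p$checksum))
    warning("training-data checksum mismatch after deserialization")
  model
}
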