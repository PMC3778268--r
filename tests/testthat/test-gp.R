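test_that("the RQ-ARD kernel evaluates its closed form", {
  # zero distance -> signal variance
  expect_equal(rq_kernel(c(1, 2), c(1, 2), signal_variance = 3.7)[1, 1], 3.7)
  # hand value: sf2=1, alpha=1, ell=1, |x - x'| = 1 -> (1 + 1/2)^-1 = 2/3
  expect_equal(rq_kernel(0, 1)[1, 1], 2 / 3)
  # symmetry
  X <- matrix(rnorm(12), 4, 3)
  K <- rq_kernel(X, X, 2, 0.7, c(1, 2, 0.5))
  expect_equal(K, t(K))
  # large alpha approaches the squared exponential
  se <- exp(-0.5 * 1)
  expect_lt(abs(rq_kernel(0, 1, alpha = 1e6)[1, 1] - se), 1e-3)
  # invalid hyperparameters rejected
  expect_error(rq_kernel(0, 1, signal_variance = -1), "positive")
})

test_that("log marginal likelihood matches dense closed-form evaluation", {
  # n = 1, y = 0, total variance 1: only the constant term survives
  r1 <- lesionprog:::gp_nlml_cpp(c(log(0.4), log(0.6), 0, 0),
                                 matrix(0, 1, 1), 0, FALSE, 1e-4)
  expect_equal(-r1$value, -0.5 * log(2 * pi), tolerance = 1e-12)

  # toy 2-point problem against the naive solve() oracle
  X <- matrix(c(0, 1.3), 2, 1)
  y <- c(0.5, -1)
  hyp <- list(sf2 = 1.5, sn2 = 0.2, alpha = 0.8, ell = 0.9)
  got <- lesionprog:::gp_nlml_cpp(log(c(hyp$sf2, hyp$sn2, hyp$alpha, hyp$ell)),
                                  X, y, FALSE, 1e-4)
  want <- oracle_gp_logml(X, y, hyp$sf2, hyp$sn2, hyp$alpha, hyp$ell)
  expect_equal(-got$value, want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("evidence gradient matches central finite differences", {
  for (s in 1:5) {
    set.seed(300 + s)
    X <- matrix(rnorm(50), 10, 5)
    y <- rnorm(10)
    theta <- rnorm(8, 0, 0.4)
    an <- lesionprog:::gp_nlml_cpp(theta, X, y, TRUE, 1e-4)
    num <- vapply(seq_along(theta), function(j) {
      e <- rep(0, 8); e[j] <- 1e-5
      f1 <- lesionprog:::gp_nlml_cpp(theta + e, X, y, FALSE, 1e-4)$value
      f2 <- lesionprog:::gp_nlml_cpp(theta - e, X, y, FALSE, 1e-4)$value
      (f1 - f2) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(num - as.numeric(an$grad)) / pmax(abs(num), 1e-6)),
              1e-4)
  }
})

test_that("predictions agree with the dense oracle on tiny problems", {
  for (s in 1:10) {
    set.seed(400 + s)
    n <- sample(1:3, 1)
    d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    hyp <- list(signal_variance = exp(rnorm(1)), noise_variance = exp(rnorm(1, -1)),
                alpha = exp(rnorm(1, 0, 0.3)), length_scales = exp(rnorm(d, 0, 0.3)))
    m <- gp_model(X, y, hyp, standardize = FALSE)
    Xs <- matrix(rnorm(5 * d), 5, d)
    got <- predict(m, Xs)
    want <- oracle_gp_predict(X, y, Xs, hyp$signal_variance,
                              hyp$noise_variance, hyp$alpha,
                              hyp$length_scales)
    expect_equal(got$mean, unname(want[, "mean"]), tolerance = 1e-8)
    expect_equal(got$variance, unname(want[, "var"]), tolerance = 1e-8)
  }
})

test_that("a single training point shrinks the target by k/(k + noise)", {
  # sf2 = sn2 = 1, x* = x_train: mean = ybar + (y - ybar) * 1/2; here the
  # centered target is y - ybar = 0 for n = 1... so use standardize = FALSE
  m <- gp_model(matrix(0, 1, 1), 4,
                list(signal_variance = 1, noise_variance = 1, alpha = 1,
                     length_scales = 1), standardize = FALSE)
  p <- predict(m, matrix(0, 1, 1))
  expect_equal(p$mean, 2)          # 4 * k/(k + sn2) = 4 * 1/2
  expect_equal(p$variance, 1 - 1 / 2 + 1)
})

test_that("near-zero noise interpolates; far queries revert to the prior", {
  set.seed(11)
  X <- matrix(runif(16, -2, 2), 8, 2)
  y <- rnorm(8, 50, 5)
  m <- gp_model(X, y, list(signal_variance = 25, noise_variance = 1e-10,
                           alpha = 1, length_scales = 1))
  at_train <- predict(m, X)
  expect_lt(max(abs(at_train$mean - y)), 1e-4)

  far <- predict(m, matrix(c(1e6, 1e6), 1, 2))
  expect_equal(far$mean, mean(y), tolerance = 1e-6)
  expect_equal(far$variance, 25 + 1e-10, tolerance = 1e-6)
})

test_that("predictive variance is positive and bounded by prior + noise", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  m <- gp_fit(X, y, control = gp_control(maxit = 40, restarts = 1), seed = 5)
  tot <- m$hyperparams$signal_variance + m$hyperparams$noise_variance
  p <- predict(m, matrix(rnorm(300, sd = 3), 100, 3))
  expect_true(all(p$variance > 0))
  expect_true(all(p$variance <= tot + 1e-8))
})

test_that("permuting training rows leaves predictions unchanged", {
  set.seed(13)
  X <- matrix(rnorm(45), 15, 3)
  y <- rnorm(15)
  Xs <- matrix(rnorm(9), 3, 3)
  perm <- sample(15)
  m1 <- gp_fit(X, y, control = gp_control(maxit = 30, restarts = 1), seed = 2)
  m2 <- gp_fit(X[perm, ], y[perm],
               control = gp_control(maxit = 30, restarts = 1), seed = 2)
  expect_equal(predict(m1, Xs), predict(m2, Xs), tolerance = 1e-6)
})

test_that("the optimizer ascends the evidence and beats the generator", {
  set.seed(14)
  n <- 60
  t <- matrix(seq(0, 10, length.out = n), ncol = 1)
  hyp_gen <- list(signal_variance = 9, noise_variance = 1, alpha = 1,
                  length_scales = 2)
  K <- rq_kernel(t, t, 9, 1, 2) + diag(1e-8, n)
  f <- drop(t(chol(K)) %*% rnorm(n))
  m <- gp_fit(t, f, control = gp_control(maxit = 100), seed = 3)
  # accepted-step trace is monotone non-increasing in nlml
  expect_true(all(diff(m$nlml_trace) <= 1e-10))
  # evidence at the optimum >= evidence at the generating hyperparameters
  at_gen <- gp_log_marginal(m, hyp_gen)$value
  expect_gte(m$evidence, at_gen - 1e-6)
})

test_that("known observation noise is recovered from simulated curves", {
  hits <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    t <- matrix(seq(1, 100, length.out = 60), ncol = 1)
    y <- 70 - 30 * exp(-t / 20) + rnorm(60, 0, 2)
    m <- gp_fit(t, y, control = gp_control(maxit = 80), seed = s)
    sn <- sqrt(m$hyperparams$noise_variance)
    if (sn > 1 && sn < 4) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("models survive JSON serialization", {
  set.seed(15)
  X <- matrix(rnorm(30), 10, 3)
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(10)
  m <- gp_fit(X, y, control = gp_control(maxit = 30, restarts = 1), seed = 1)
  f <- tempfile(fileext = ".json")
  gp_save(m, f)
  m2 <- gp_load(f)
  Xs <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(m2, Xs), predict(m, Xs), tolerance = 1e-12)
  expect_equal(m2$hyperparams, m$hyperparams, tolerance = 1e-12)
})
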