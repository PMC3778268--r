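test_that("actual-on-predicted regression matches the OLS closed form", {
  expect_equal(regress_actual_on_predicted(1:4, 1:4)$r2, 1)
  conv <- regress_actual_on_predicted(c(1, 2, 3), c(2, 2, 2))
  expect_equal(conv[c("r2", "f_stat", "p_value")], list(r2 = 0, f_stat = 0,
                                                        p_value = 1))
  actual <- c(1, 2, 3, 4)
  pred <- c(1.1, 1.9, 3.2, 3.8)
  got <- regress_actual_on_predicted(actual, pred)
  want <- oracle_ols_r2(actual, pred)
  expect_equal(got$r2, want$r2, tolerance = 1e-10)
  expect_equal(got$f_stat, want$f, tolerance = 1e-10)
  expect_equal(got$p_value, pf(want$f, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("R2 is scale-invariant but the error SD is not", {
  set.seed(21)
  actual <- rnorm(30, 50, 8)
  pred <- actual + rnorm(30, 0, 3)
  r2 <- regress_actual_on_predicted(actual, pred)$r2
  expect_equal(regress_actual_on_predicted(actual, 2 * pred + 7)$r2, r2,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(error_sd(actual, 2 * pred + 7),
                                error_sd(actual, pred))))
})

test_that("error SD uses the n-1 denominator and ignores constant offsets", {
  expect_equal(error_sd(c(5, 5), c(5, 5)), 0)
  expect_equal(error_sd(c(1, -1), c(0, 0)), sqrt(2))
  set.seed(22)
  a <- rnorm(20); p <- rnorm(20)
  expect_equal(error_sd(a + 3, p), error_sd(a, p), tolerance = 1e-12)
})

test_that("paired Wilcoxon Z matches exact enumeration and wilcox.test", {
  # identical vectors: all differences zero
  same <- compare_errors_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same[c("z", "p_value")], list(z = 0, p_value = 1))

  # n = 6, all differences positive: W+ must equal the enumeration maximum
  a <- c(5, 6, 7, 8, 9, 10); b <- c(1, 2, 3, 4, 5, 6)
  got <- compare_errors_wilcoxon(a, b)
  want <- oracle_signed_rank(a - b)
  expect_equal(got$statistic, want$w)
  expect_equal(want$w, 21)  # maximum possible at n = 6
  # normal-approximation p close to the exact p
  expect_lt(abs(got$p_value - want$p_exact), 0.02)

  # antisymmetry
  expect_equal(compare_errors_wilcoxon(b, a)$z, -got$z)

  # agreement with stats::wilcox.test normal approximation across cases
  set.seed(23)
  for (i in 1:10) {
    x <- round(rnorm(15, 0, 2), 1)
    y <- round(rnorm(15, 0.5, 2), 1)
    keep <- (x - y) != 0
    if (sum(keep) < 3) next
    ours <- compare_errors_wilcoxon(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x[keep], y[keep], paired = TRUE, exact = FALSE,
                         correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("AUC equals brute-force pairwise concordance", {
  # perfectly separated and fully tied cases
  expect_equal(roc_auc(c(40, 45, 65, 70), c(50, 55, 65, 70),
                       n_boot = 0)$auc, 1)
  expect_equal(roc_auc(rep(60, 6), c(50, 50, 55, 65, 70, 70),
                       n_boot = 0)$auc, 0.5)
  expect_error(roc_auc(1:4, c(70, 71, 72, 73)), "both")

  set.seed(24)
  for (i in 1:20) {
    pred <- sample(seq(40, 80, by = 5), 20, replace = TRUE)  # force ties
    actual <- rnorm(20, 60, 6)
    if (all(actual < 60) || all(actual >= 60)) next
    got <- roc_auc(pred, actual, n_boot = 0)$auc
    expect_equal(got, oracle_auc(pred, actual < 60), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC and the bootstrap CI brackets it", {
  set.seed(25)
  actual <- rnorm(60, 60, 6)
  pred <- actual + rnorm(60, 0, 4)
  res <- roc_auc(pred, actual, n_boot = 500, seed = 9)
  ref <- as.numeric(pROC::auc(pROC::roc(actual < 60, pred, quiet = TRUE,
                                        direction = ">")))
  expect_equal(res$auc, ref, tolerance = 1e-12)
  expect_lte(res$ci[1], res$auc)
  expect_gte(res$ci[2], res$auc)
  # seeded bootstrap is reproducible
  res2 <- roc_auc(pred, actual, n_boot = 500, seed = 9)
  expect_identical(res$ci, res2$ci)
})

test_that("leave-one-out runs one fold per patient", {
  coh <- small_cohort(12, seed = 31)
  first <- split_visits(coh$records)$first
  v <- loocv_cross_sectional(first, "dem_lv",
                             control = gp_control(maxit = 20, restarts = 1),
                             seed = 1)
  expect_equal(nrow(v$predictions), nrow(first))
  expect_true(all(is.finite(v$predictions$predicted_mean)))
  expect_equal(v$predictions$patient_id, first$patient_id)
  # duplicate patients rejected
  expect_error(loocv_cross_sectional(rbind(first, first[1, ]), "dem"),
               "one record per patient")
})

test_that("shuffled targets yield near-zero cross-validated R2", {
  coh <- small_cohort(40, seed = 32)
  first <- split_visits(coh$records)$first
  set.seed(33)
  first$speech_score <- sample(first$speech_score)
  v <- loocv_cross_sectional(first, "atlas",
                             control = gp_control(maxit = 40, restarts = 1),
                             seed = 2)
  expect_lt(v$r2, 0.1)
})

test_that("longitudinal evaluation predicts repeat visits from one fit", {
  coh <- small_cohort(40, seed = 34, repeat_prob = 0.4)
  sv <- split_visits(coh$records)
  expect_gt(nrow(sv$repeats), 2)
  v <- longitudinal_eval(sv$first, sv$repeats, "atlas",
                         control = gp_control(maxit = 40, restarts = 1),
                         seed = 3)
  expect_equal(nrow(v$predictions), nrow(sv$repeats))
  expect_true(all(v$predictions$in_training))

  # a repeat record identical to its training record gets the in-sample
  # prediction for that training point
  clone <- sv$first[1, ]
  clone$visit_index <- 2L
  v2 <- longitudinal_eval(sv$first, clone, "atlas",
                          control = gp_control(maxit = 40, restarts = 1),
                          seed = 3)
  in_sample <- predict(v2$model, feature_matrix(sv$first[1, ], "atlas"))
  expect_equal(v2$predictions$predicted_mean, in_sample$mean)

  # unknown patients are flagged but still predicted
  ghost <- clone; ghost$patient_id <- "GHOST"
  expect_warning(v3 <- longitudinal_eval(sv$first, ghost, "atlas",
                                         control = gp_control(maxit = 20,
                                                              restarts = 1),
                                         seed = 3),
                 "absent from training")
  expect_false(v3$predictions$in_training)
  expect_true(is.finite(v3$predictions$predicted_mean))

  # zero repeat records: empty result, no error
  v0 <- longitudinal_eval(sv$first, sv$repeats[0, ], "atlas")
  expect_equal(nrow(v0$predictions), 0)
})
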