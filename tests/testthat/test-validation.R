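test_that("AUC hits the trivial limits", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoid AUC equals the exhaustive pair-count oracle", {
  set.seed(16)
  for (i in 1:5) {
    scores <- round(rnorm(30), 1)  # rounding forces ties
    labels <- rbinom(30, 1, plogis(scores))
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, brute_force_auc(scores, labels), tolerance = 1e-12)
    expect_gte(r$auc, r$auc_ci[1])
    expect_lte(r$auc, r$auc_ci[2])
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(17)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(2 * scores))
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels)$auc, a,
               tolerance = 1e-12)
})

test_that("AUC and DeLong comparison agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(18)
  labels <- rbinom(120, 1, 0.4)
  a <- rnorm(120, labels)
  b <- rnorm(120, 0.5 * labels)
  r <- roc_auc(a, labels)
  pr <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc_ci, ci[c(1, 3)], tolerance = 1e-8)
  cmp <- compare_auc(a, b, labels)
  pt <- pROC::roc.test(pr, pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, pt$p.value, tolerance = 1e-8)
})

test_that("paired comparison of identical or rank-equal scores gives p = 1", {
  set.seed(19)
  labels <- rbinom(50, 1, 0.5)
  s <- rnorm(50, labels)
  same <- compare_auc(s, s, labels)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_difference, 0)
  mono <- compare_auc(s, plogis(3 * s + 2), labels)
  expect_equal(mono$auc_difference, 0)
  expect_equal(mono$p_value, 1)
  expect_error(compare_auc(s, s[-1], labels), "length")
})

test_that("DeLong comparison holds its type-I error rate", {
  set.seed(20)
  n <- 400
  rej <- mean(replicate(1000, {
    labels <- rep(0:1, each = n / 2)
    compare_auc(rnorm(n), rnorm(n), labels)$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("an in-sample ML fit recalibrates to slope 1 and CITL 0", {
  sc <- generate_scenarios(default_catalog(), 400, seed = 21)
  y <- simulate_outcomes(sc, published_generating_model(seed = 21L))$outcome
  fit <- fit_complexity(score_columns(sc), y)
  cal <- calibration_metrics(predict(fit, type = "response"), y)
  expect_lt(abs(cal$slope - 1), 1e-6)
  expect_lt(abs(cal$citl), 1e-6)
  expect_equal(sum(cal$bins$n), length(y))
  expect_true(all(cal$bins$observed_fraction >= 0 &
                    cal$bins$observed_fraction <= 1))
  expect_true(all(cal$bins$n >= 5))
})

test_that("halved logits are detected as a calibration slope near 2", {
  set.seed(22)
  lp <- rnorm(20000, 0, 2)
  y <- rbinom(20000, 1, plogis(lp))
  cal <- calibration_metrics(plogis(lp / 2), y)
  expect_lt(abs(cal$slope - 2), 0.1)
})

test_that("degenerate predictions are rejected", {
  y <- rep(0:1, 10)
  expect_error(calibration_metrics(rep(0.4, 20), y), "zero variance")
  expect_error(calibration_metrics(c(0, runif(19)), y), "strictly inside")
})

test_that("predictive values match hand-counted contingency tables", {
  scores <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  labels <- c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1)
  pv <- predictive_values(scores, labels, c(3, 6, 9))
  # t = 3: above = scores 3..10 (8 cases, 5 complex); below = {1,2} (0 complex)
  expect_equal(pv$ppv[pv$threshold == 3], 5 / 8)
  expect_equal(pv$npv[pv$threshold == 3], 1)
  # t = 6: above = 6..10 (5 cases, 4 complex); below = 1..5 (1 complex of 5)
  expect_equal(pv$ppv[pv$threshold == 6], 4 / 5)
  expect_equal(pv$npv[pv$threshold == 6], 4 / 5)
  # t = 9: above = {9,10} both complex; below = 3 complex of 8
  expect_equal(pv$ppv[pv$threshold == 9], 1)
  expect_equal(pv$npv[pv$threshold == 9], 5 / 8)
  expect_equal(pv$n_above, c(8L, 5L, 2L))
})

test_that("empty sides are undefined (NA), not zero", {
  labels <- rep(1, 6)
  labels[1] <- 0  # prevalence 5/6
  pv <- predictive_values(1:6, labels, c(0.5, 100))
  expect_equal(pv$ppv[1], 5 / 6)
  expect_true(is.na(pv$npv[1]))   # nothing below the minimum
  expect_true(is.na(pv$ppv[2]))   # nothing above the maximum
  expect_equal(pv$npv[2], 1 / 6)  # 1 - prevalence
  all_pos <- predictive_values(1:6, rep(1, 6), 3)
  expect_equal(all_pos$ppv, 1)
})

test_that("PPV rises and NPV falls along thresholds under a monotone score", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20000
    y <- rbinom(n, 1, 0.5)
    s <- rnorm(n, y)  # monotone likelihood ratio in s
    thr <- stats::quantile(s, seq(0.1, 0.9, 0.1))
    pv <- predictive_values(s, y, thr)
    expect_true(all(diff(pv$ppv) >= -0.02))
    expect_true(all(diff(pv$npv) <= 0.02))
  }
})

test_that("plot methods draw without error", {
  set.seed(23)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60, y)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_no_error(plot(roc_auc(s, y)))
  expect_no_error(plot(calibration_metrics(plogis(s), y)))
  expect_no_error(plot(predictive_values(s, y, quantile(s, c(0.25, 0.5, 0.75)))))
})
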