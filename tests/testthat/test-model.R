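test_that("Mann-Whitney recovers exact symmetric and separated cases", {
  sym <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$method, "exact_enumeration")

  sep <- mann_whitney(c(1, 1, 1), c(2, 2, 2))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)  # 2/20 assignments, enumeration oracle
})

test_that("normal approximation stays within 0.05 of exact enumeration", {
  vals <- c(0.4, 1.1, 1.9, 2.3, 3.0, 3.8, 4.4, 5.2)
  for (nx in 2:6) {
    for (pick in utils::combn(8, nx, simplify = FALSE)) {
      x <- vals[pick]; y <- vals[-pick]
      p_norm <- mann_whitney(x, y, exact_max = 0)$p_value
      expect_lt(abs(p_norm - enumerate_mw_p(x, y)), 0.05)
    }
  }
})

test_that("Mann-Whitney is antisymmetric and agrees with wilcox.test", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  a <- mann_whitney(x, y)
  b <- mann_whitney(y, x)
  expect_equal(b$statistic, length(x) * length(y) - a$statistic)
  expect_equal(a$p_value, b$p_value)
  # tie-free data: matches the classical normal approximation
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(a$statistic, unname(w$statistic))
  expect_equal(a$p_value, w$p.value, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), y), "non-empty")
})

test_that("the univariate screen applies a strict threshold", {
  expect_equal(screen_domains(c(history = 0.07, age = 0.85)), "history")
  expect_equal(screen_domains(c(d = 0.1)), character(0))
  expect_equal(screen_domains(c(a = 0.2, b = 0.9)), character(0))
})

test_that("degenerate outcomes and separation are rejected with clear errors", {
  set.seed(2)
  sc <- matrix(sample(1:5, 100, TRUE), 20, 5,
               dimnames = list(NULL, c("history", "access", "number", "size",
                                       "location")))
  expect_error(fit_complexity(sc, rep(0L, 20)), "degenerate outcome")
  y <- ifelse(sc[, "size"] >= 3, 1L, 0L)
  expect_error(fit_complexity(sc, y), "separation.*'size'")
})

test_that("a mirror-symmetric design has intercept zero", {
  set.seed(3)
  half <- matrix(rnorm(200), 40, 5,
                 dimnames = list(NULL, c("history", "access", "number", "size",
                                         "location")))
  scores <- rbind(half, -half)  # mirrored around 0
  y <- c(rep(1L, 40), rep(0L, 40))
  fit <- fit_complexity(scores, y)
  expect_lt(abs(fit$intercept), 1e-6)
  expect_true(fit$converged)
})

test_that("in-sample mean predicted probability equals prevalence", {
  sc <- generate_scenarios(default_catalog(), 300, seed = 6)
  gm <- published_generating_model(seed = 6L)
  y <- simulate_outcomes(sc, gm)$outcome
  fit <- fit_complexity(score_columns(sc), y)
  expect_lt(abs(mean(predict(fit, type = "response")) - mean(y)), 1e-8)
})

test_that("fitting recovers the generating coefficients within 3 SE", {
  sc <- generate_scenarios(default_catalog(), 4000, seed = 100)
  gm <- published_generating_model(scenario_scale = 0, seed = 100L)
  y <- simulate_outcomes(sc, gm)$outcome
  fit <- fit_complexity(score_columns(sc), y)
  expect_true(fit$converged)
  truth <- c("(Intercept)" = gm$intercept, gm$coefficients)
  est <- coef(fit)[names(truth)]
  se <- c(fit$intercept_se, fit$std_errors[names(gm$coefficients)])
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("the probability function reproduces published anchor values", {
  m <- published_model()
  all1 <- c(history = 1, access = 1, number = 1, size = 1, location = 1)
  all5 <- c(history = 5, access = 5, number = 5, size = 5, location = 5)
  expect_equal(predict_probability(m, all1), 4.054936e-4, tolerance = 1e-6)
  expect_gt(predict_probability(m, all5), predict_probability(m, all1))
  expect_error(predict_probability(m, all1[-2]), "access")
  # strictly increasing in each score when coefficients are positive
  for (d in names(m$coefficients)) {
    bumped <- all1; bumped[d] <- 2
    expect_gt(predict_probability(m, bumped), predict_probability(m, all1))
  }
  zero <- m; zero$intercept <- 0; zero$coefficients[] <- 0
  expect_equal(predict_probability(zero, all1), 0.5)
})

test_that("model JSON serialization round-trips", {
  sc <- generate_scenarios(default_catalog(), 200, seed = 9)
  y <- simulate_outcomes(sc, published_generating_model(seed = 9L))$outcome
  fit <- fit_complexity(score_columns(sc), y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$std_errors, fit$std_errors)
  expect_equal(unname(back$covariance), unname(fit$covariance),
               tolerance = 1e-12)
})

test_that("model methods expose the usual modelling surface", {
  sc <- generate_scenarios(default_catalog(), 200, seed = 10)
  y <- simulate_outcomes(sc, published_generating_model(seed = 10L))$outcome
  fit <- fit_complexity(score_columns(sc), y)
  s <- summary(fit)
  expect_s3_class(s, "summary.bcc_model")
  expect_equal(rownames(s$table)[1], "(Intercept)")
  expect_equal(dim(vcov(fit)), c(6, 6))
  expect_output(print(fit), "Logistic complexity model")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(200L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_identical(simulate(fit, nsim = 2, seed = 4),
                   simulate(fit, nsim = 2, seed = 4))
  expect_length(residuals(fit), 200)
})
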