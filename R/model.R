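# The complexity model: univariate Mann-Whitney screen, maximum-likelihood
# logistic regression of panel-judged complexity on the five domain scores,
# and the logistic probability function. The fitted object is an S3 class
# ("bcc_model") with the usual modelling methods.

#' Two-sample Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The two-tailed
#' p-value uses exact enumeration of all assignments when the combined
#' sample size is at most `exact_max` (default 12), and the tie-corrected,
#' continuity-corrected normal approximation otherwise.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Combined-size cutoff for exact enumeration.
#' @return List of class `"bcc_stat"` with `statistic` (U of `x`),
#'   `p_value`, and `method` (`"exact_enumeration"` or
#'   `"normal_tie_corrected"`).
#' @export
#' @examples
#' mann_whitney(c(1, 1, 1), c(2, 2, 2))  # U = 0, exact p = 0.1
mann_whitney <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop_bccs("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y))
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_max) {
    idx <- utils::combn(nx + ny, nx)
    us <- apply(idx, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact_enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_tie_corrected"
  }
  structure(list(statistic = u, p_value = p, method = method),
            class = "bcc_stat")
}

#' @export
print.bcc_stat <- function(x, ...) {
  cat(sprintf("statistic = %g, p = %.4g (%s)\n", x$statistic, x$p_value,
              x$method))
  invisible(x)
}

#' Univariate screen: domains entering the multivariable model
#'
#' Retains exactly the domains with p strictly below `alpha` (default 0.1,
#' the liberal entry threshold that lets borderline predictors such as
#' patient history into the multivariable fit).
#'
#' @param domain_pvalues Named numeric vector of p-values in `[0, 1]`.
#' @param alpha Entry threshold.
#' @return Character vector of retained domain names.
#' @export
screen_domains <- function(domain_pvalues, alpha = 0.1) {
  stopifnot(is.numeric(domain_pvalues), !is.null(names(domain_pvalues)),
            all(domain_pvalues >= 0 & domain_pvalues <= 1))
  names(domain_pvalues)[domain_pvalues < alpha]
}

#' Univariate Mann-Whitney screen of scenario domain scores
#'
#' For each predictor domain, compares the domain scores of scenarios judged
#' complex against those judged not complex.
#'
#' @param scores Matrix or data frame of per-scenario domain scores.
#' @param outcome Binary outcome (0 = not complex, 1 = complex).
#' @return Data frame with `domain`, `statistic`, `p_value`.
#' @export
screen_scores <- function(scores, outcome) {
  scores <- as.matrix(scores)
  stopifnot(length(outcome) == nrow(scores), all(outcome %in% 0:1))
  out <- do.call(rbind, lapply(colnames(scores), function(d) {
    s <- mann_whitney(scores[outcome == 1, d], scores[outcome == 0, d])
    data.frame(domain = d, statistic = s$statistic, p_value = s$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

detect_separation <- function(scores, outcome) {
  for (d in colnames(scores)) {
    x0 <- scores[outcome == 0, d]
    x1 <- scores[outcome == 1, d]
    if (max(x0) < min(x1) || max(x1) < min(x0)) return(d)
  }
  NULL
}

#' Fit the logistic complexity model
#'
#' Maximum-likelihood logistic regression of a binary complexity outcome on
#' per-scenario domain scores (the Median Opinions of the selected items,
#' treated as numeric). Fitting is iteratively reweighted least squares via
#' [stats::glm()] with a tight convergence tolerance (1e-10, at most 100
#' iterations); standard errors come from the inverse observed information.
#' Complete separation on any single domain is detected before fitting and
#' reported as an error naming the domain.
#'
#' @param scores Matrix or data frame, scenarios x domains.
#' @param outcome Binary vector (0/1) with both classes present.
#' @return An object of class `"bcc_model"`: a list with `intercept`,
#'   `coefficients` (named, per domain), `std_errors`, `covariance`,
#'   `converged`, `n_obs`, plus the underlying `glm` fit. Supports `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `simulate` and `residuals`.
#' @export
#' @examples
#' cat <- default_catalog()
#' sc <- generate_scenarios(cat, 200, seed = 1)
#' gm <- published_generating_model(seed = 1)
#' y <- simulate_outcomes(sc, gm, seed = 1)$outcome
#' fit <- fit_complexity(sc[, paste0("score_", c("history", "access",
#'   "number", "size", "location"))], y)
#' summary(fit)
fit_complexity <- function(scores, outcome) {
  scores <- as.matrix(scores)
  colnames(scores) <- sub("^score_", "", colnames(scores))
  storage.mode(scores) <- "double"
  if (nrow(scores) < 10L) {
    stop_bccs("at least 10 observations are required, got %d", nrow(scores))
  }
  if (length(outcome) != nrow(scores)) {
    stop_bccs("outcome length (%d) does not match score rows (%d)",
              length(outcome), nrow(scores))
  }
  if (anyNA(outcome) || !all(outcome %in% 0:1)) {
    stop_bccs("outcome must be 0/1 with no missing values")
  }
  if (length(unique(outcome)) < 2L) {
    stop_bccs("degenerate outcome: both classes must be present")
  }
  sep <- detect_separation(scores, outcome)
  if (!is.null(sep)) {
    stop_bccs("complete separation detected on domain '%s'", sep)
  }
  df <- data.frame(scores, check.names = FALSE)
  df$.outcome <- as.integer(outcome)
  fml <- stats::as.formula(paste(".outcome ~",
                                 paste(sprintf("`%s`", colnames(scores)),
                                       collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  se <- sqrt(diag(vc))
  converged <- isTRUE(fit$converged) && all(is.finite(se)) && max(abs(cf)) < 50
  structure(list(intercept = unname(cf[1L]),
                 coefficients = stats::setNames(unname(cf[-1L]),
                                                colnames(scores)),
                 std_errors = stats::setNames(unname(se[-1L]),
                                              colnames(scores)),
                 intercept_se = unname(se[1L]),
                 covariance = vc,
                 converged = converged,
                 n_obs = nrow(scores),
                 provenance = "fitted",
                 glm = fit),
            class = "bcc_model")
}

#' The published complexity model
#'
#' Loads the packaged fixture of the published logistic regression
#' (intercept -13.34; history 0.99, number 0.96, location 1.44, size 1.04,
#' access 1.10; n = 131). Only marginal standard errors were published, so
#' the covariance slot is the diagonal approximation.
#'
#' @return A `"bcc_model"` with provenance `"published"`.
#' @export
#' @examples
#' predict_probability(published_model(),
#'   c(history = 1, access = 1, number = 1, size = 1, location = 1))
published_model <- function() {
  read_model(system.file("extdata", "table2.json", package = "bccs",
                         mustWork = TRUE))
}

#' Read a serialized complexity model
#'
#' @param path JSON file with `intercept`, `coefficients`, `std_errors` and
#'   optionally `covariance` and `n_obs`.
#' @return A `"bcc_model"`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("intercept", "coefficients", "std_errors")
  miss <- setdiff(need, names(j))
  if (length(miss)) {
    stop_bccs("model file '%s' lacks fields: %s", path,
              paste(miss, collapse = ", "))
  }
  cf <- unlist(j$coefficients)
  se <- unlist(j$std_errors)
  if (!identical(sort(names(cf)), sort(names(se)))) {
    stop_bccs("coefficient and std_error names differ in '%s'", path)
  }
  se <- se[names(cf)]
  vc <- if (!is.null(j$covariance)) {
    as.matrix(j$covariance)
  } else {
    diag(c(j$intercept_se %||% NA_real_, se)^2)
  }
  dimnames(vc) <- list(c("(Intercept)", names(cf)), c("(Intercept)", names(cf)))
  structure(list(intercept = j$intercept,
                 coefficients = cf,
                 std_errors = se,
                 intercept_se = j$intercept_se %||% sqrt(vc[1L, 1L]),
                 covariance = vc,
                 converged = TRUE,
                 n_obs = j$n_obs %||% NA_integer_,
                 provenance = j$provenance %||% "file"),
            class = "bcc_model")
}

#' Serialize a complexity model to JSON
#'
#' @param model A `"bcc_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bcc_model"))
  jsonlite::write_json(
    list(provenance = model$provenance,
         n_obs = model$n_obs,
         intercept = model$intercept,
         intercept_se = model$intercept_se,
         coefficients = as.list(model$coefficients),
         std_errors = as.list(model$std_errors),
         covariance = unname(apply(model$covariance, 1, as.list))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Probability of a complex resection for one case
#'
#' Evaluates the logistic probability function
#' `p = 1 / (1 + exp(-(intercept + sum(coef_d * score_d))))` for a full set
#' of domain scores.
#'
#' @param model A `"bcc_model"`.
#' @param domain_scores Named vector (or one-row data frame) of scores 1..5
#'   covering every model domain.
#' @return Probability in (0, 1).
#' @export
predict_probability <- function(model, domain_scores) {
  stopifnot(inherits(model, "bcc_model"))
  if (is.data.frame(domain_scores)) domain_scores <- unlist(domain_scores[1L, ])
  miss <- setdiff(names(model$coefficients), names(domain_scores))
  if (length(miss)) {
    stop_bccs("missing domain score(s): %s", paste(miss, collapse = ", "))
  }
  s <- domain_scores[names(model$coefficients)]
  unname(stats::plogis(model$intercept + sum(model$coefficients * s)))
}

# ---- S3 methods --------------------------------------------------------

#' @export
coef.bcc_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
vcov.bcc_model <- function(object, ...) object$covariance

#' @export
print.bcc_model <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic complexity model (%s%s)\n", x$provenance,
              if (!is.na(x$n_obs)) sprintf(", n = %d", x$n_obs) else ""))
  print(round(coef(x), digits))
  if (!isTRUE(x$converged)) cat("warning: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
summary.bcc_model <- function(object, ...) {
  est <- coef(object)
  se <- c(object$intercept_se, object$std_errors)
  z <- est / se
  tab <- data.frame(estimate = est, std_error = se, z = z,
                    p_value = 2 * stats::pnorm(-abs(z)),
                    ci_low = est - stats::qnorm(0.975) * se,
                    ci_high = est + stats::qnorm(0.975) * se)
  structure(list(table = tab, n_obs = object$n_obs,
                 converged = object$converged,
                 provenance = object$provenance),
            class = "summary.bcc_model")
}

#' @export
print.summary.bcc_model <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic complexity model (%s%s)\n", x$provenance,
              if (!is.na(x$n_obs)) sprintf(", n = %d", x$n_obs) else ""))
  print(round(x$table, digits))
  invisible(x)
}

model_linear_predictor <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    cols <- names(newdata)
    sc_cols <- paste0("score_", names(model$coefficients))
    if (all(sc_cols %in% cols)) {
      newdata <- newdata[, sc_cols, drop = FALSE]
      names(newdata) <- names(model$coefficients)
    }
    newdata <- as.matrix(newdata)
  }
  newdata <- as.matrix(newdata)
  miss <- setdiff(names(model$coefficients), colnames(newdata))
  if (length(miss)) {
    stop_bccs("newdata lacks domain score(s): %s", paste(miss, collapse = ", "))
  }
  model$intercept +
    as.vector(newdata[, names(model$coefficients), drop = FALSE] %*%
                model$coefficients)
}

#' Predict complexity probabilities
#'
#' @param object A `"bcc_model"`.
#' @param newdata Matrix or data frame of domain scores (columns named after
#'   the model domains, or `score_<domain>` as produced by
#'   [generate_scenarios()]). Defaults to the training data for fitted
#'   models.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... Unused.
#' @export
predict.bcc_model <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$glm)) {
      stop_bccs("'newdata' is required for a model without stored training data")
    }
    lp <- stats::predict(object$glm, type = "link")
  } else {
    lp <- model_linear_predictor(object, newdata)
  }
  if (type == "link") unname(lp) else unname(stats::plogis(lp))
}

#' Simulate binary outcomes from a fitted complexity model
#'
#' @param object A `"bcc_model"`.
#' @param nsim Number of replicate outcome vectors.
#' @param seed Integer seed or `NULL`.
#' @param newdata Optional domain scores; defaults to the training data.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.bcc_model <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                               ...) {
  p <- predict(object, newdata = newdata, type = "response")
  with_rng(seed, {
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
residuals.bcc_model <- function(object, ...) {
  if (is.null(object$glm)) {
    stop_bccs("residuals are only available for fitted models")
  }
  stats::residuals(object$glm, ...)
}
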