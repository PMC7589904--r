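# Synthetic expert panel. The study's raw panel responses were never
# published, so a generative stand-in reproduces their statistical
# structure: latent item complexities rated on a 1..5 Likert scale with
# Gaussian perturbation, a second round attracted toward the first-round
# median (the feedback the panel received), and scenario ratings driven by
# a logistic generating model.

#' Panel noise model
#'
#' @param noise_sd Standard deviation of the Gaussian perturbation applied to
#'   an item's latent complexity before rounding to the Likert grid. The
#'   default 1.4 yields first-round consensus on roughly half the items for a
#'   10-member panel, matching a strongly but not perfectly concordant panel.
#' @param convergence Attraction of second-round responses toward the
#'   first-round median, in `[0, 1]`; 0 leaves responses unchanged, 1 makes
#'   every panelist report the median. Default 0.7 brings nearly all items to
#'   consensus in round two.
#' @param seed Integer seed for the simulation stream, or `NULL` to draw from
#'   the current stream.
#' @return A list of class `"panel_noise_model"`.
#' @export
panel_noise_model <- function(noise_sd = 1.4, convergence = 0.7, seed = NULL) {
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
            is.numeric(convergence), length(convergence) == 1L,
            convergence >= 0, convergence <= 1)
  structure(list(noise_sd = noise_sd, convergence = convergence, seed = seed),
            class = "panel_noise_model")
}

#' First-round Likert responses for a set of items
#'
#' Each response is `clamp(round(latent + N(0, noise_sd)), 1, 5)`.
#'
#' @param truths Data frame with columns `item_id` and `latent_complexity`
#'   (reals in `[1, 5]`), or a named numeric vector of latent complexities.
#' @param n_panelists Number of panelists (>= 1).
#' @param noise A [panel_noise_model()].
#' @return Integer matrix, `n_panelists` x `nrow(truths)`, with panelist row
#'   names and item column names.
#' @export
#' @examples
#' tr <- data.frame(item_id = c("a", "b"), latent_complexity = c(2, 4.5))
#' simulate_item_responses(tr, 10, panel_noise_model(seed = 1))
simulate_item_responses <- function(truths, n_panelists,
                                    noise = panel_noise_model()) {
  if (is.numeric(truths)) {
    truths <- data.frame(item_id = names(truths) %||% paste0("item_", seq_along(truths)),
                         latent_complexity = as.numeric(truths),
                         stringsAsFactors = FALSE)
  }
  if (!is.data.frame(truths) || nrow(truths) == 0L) {
    stop_bccs("'truths' must be a non-empty data frame of item truths")
  }
  stopifnot(all(c("item_id", "latent_complexity") %in% names(truths)))
  lat <- truths$latent_complexity
  if (any(!is.finite(lat) | lat < 1 | lat > 5)) {
    stop_bccs("latent complexities must lie in [1, 5]")
  }
  stopifnot(is.numeric(n_panelists), length(n_panelists) == 1L, n_panelists >= 1)
  n_panelists <- as.integer(n_panelists)
  m <- with_rng(noise$seed, {
    eps <- matrix(stats::rnorm(n_panelists * nrow(truths), 0, noise$noise_sd),
                  n_panelists, nrow(truths))
    clamp_likert(round(rep(lat, each = n_panelists) + eps))
  })
  m <- matrix(m, n_panelists, nrow(truths),
              dimnames = list(paste0("panelist_", seq_len(n_panelists)),
                              truths$item_id))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Second Delphi round: confirm or adjust toward the panel median
#'
#' Each response moves toward its item's first-round median by the factor
#' `convergence` and is re-rounded to the Likert grid:
#' `clamp(round((1 - c) * response + c * median), 1, 5)`. The adjustment is
#' deterministic given round one.
#'
#' @param round1 Integer response matrix from [simulate_item_responses()].
#' @param noise A [panel_noise_model()]; only `convergence` is used.
#' @return Integer matrix of the same shape as `round1`.
#' @export
simulate_round2 <- function(round1, noise = panel_noise_model()) {
  round1 <- as_response_matrix(round1)
  check_likert_values(round1, "round-1 response")
  cv <- noise$convergence
  med <- apply(round1, 2, stats::median)
  out <- clamp_likert(round((1 - cv) * round1 +
                              cv * matrix(med, nrow(round1), ncol(round1), byrow = TRUE)))
  matrix(out, nrow(round1), ncol(round1), dimnames = dimnames(round1))
}

#' Logistic generating model for scenario ratings
#'
#' The generative truth behind synthetic scenario ratings. A scenario's
#' latent probability of complex surgery is
#' `plogis(intercept + sum(coef[d] * score[d]) + u)`, where `u` is a shared
#' scenario-level heterogeneity term, logistic on the logit scale with scale
#' `scenario_scale`. The term reflects that a panel reacts to the whole
#' vignette, not only to the five scored domains; without it panel verdicts
#' would be a deterministic function of the domain scores. Each panelist then
#' perturbs the probability by `N(0, rating_noise_sd)` and reports the Likert
#' band of the result under `cutpoints`.
#'
#' @param intercept Intercept on the logit scale.
#' @param coefficients Named numeric vector of per-domain slopes (the five
#'   predictor domains).
#' @param cutpoints Four strictly increasing probabilities partitioning
#'   `[0, 1]` into the five Likert bands. The default `(0.05, 0.2, 0.5, 0.8)`
#'   places "may occasionally" (3) across the middle probabilities.
#' @param rating_noise_sd Panelist perturbation on the probability scale;
#'   default 0.10.
#' @param scenario_scale Scale of the shared scenario-level logistic
#'   heterogeneity on the logit scale; default 1.0. Set 0 to disable.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `"generating_model"`.
#' @export
generating_model <- function(intercept, coefficients,
                             cutpoints = c(0.05, 0.2, 0.5, 0.8),
                             rating_noise_sd = 0.10,
                             scenario_scale = 1.0,
                             seed = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)),
            length(cutpoints) == 4L, all(diff(cutpoints) > 0),
            all(cutpoints > 0 & cutpoints < 1),
            rating_noise_sd >= 0, scenario_scale >= 0)
  structure(list(intercept = intercept, coefficients = coefficients,
                 cutpoints = cutpoints, rating_noise_sd = rating_noise_sd,
                 scenario_scale = scenario_scale, seed = seed),
            class = "generating_model")
}

#' The published-coefficient generating model
#'
#' [generating_model()] with the published regression estimates (intercept
#' -13.34; history 0.99, number 0.96, location 1.44, size 1.04, access 1.10)
#' used as the generative truth.
#'
#' @inheritParams generating_model
#' @return A `"generating_model"`.
#' @export
published_generating_model <- function(rating_noise_sd = 0.10,
                                       scenario_scale = 1.0, seed = NULL) {
  m <- published_model()
  generating_model(m$intercept, m$coefficients,
                   rating_noise_sd = rating_noise_sd,
                   scenario_scale = scenario_scale, seed = seed)
}

scenario_scores <- function(scenarios, domains) {
  cols <- paste0("score_", domains)
  miss <- setdiff(cols, names(scenarios))
  if (length(miss)) {
    stop_bccs("scenarios lack domain scores: %s",
              paste(sub("^score_", "", miss), collapse = ", "))
  }
  m <- as.matrix(scenarios[, cols, drop = FALSE])
  colnames(m) <- domains
  m
}

#' Latent complexity probabilities of scenarios under a generating model
#'
#' @param scenarios Scenario data frame from [generate_scenarios()].
#' @param model A [generating_model()].
#' @param seed Seed for the scenario-level heterogeneity draw (`NULL`: the
#'   model's own seed).
#' @return Numeric vector of probabilities, one per scenario.
#' @export
scenario_probabilities <- function(scenarios, model, seed = NULL) {
  sc <- scenario_scores(scenarios, names(model$coefficients))
  lp <- model$intercept + as.vector(sc %*% model$coefficients)
  seed <- seed %||% model$seed
  u <- if (model$scenario_scale > 0) {
    with_rng(if (is.null(seed)) NULL else stage_seed(seed, "scenario_effect"),
             stats::rlogis(nrow(sc), 0, model$scenario_scale))
  } else {
    rep(0, nrow(sc))
  }
  stats::plogis(lp + u)
}

#' Panel ratings of clinical scenarios
#'
#' Computes each scenario's latent probability via the generating model and
#' lets each panelist report the Likert band of `p + N(0, rating_noise_sd)`
#' under the model's cutpoints, clamped to 1..5.
#'
#' @param scenarios Scenario data frame with one `score_<domain>` column per
#'   generating-model domain.
#' @param model A [generating_model()].
#' @param n_panelists Number of panelists (>= 1).
#' @param seed Seed (`NULL`: the model's own seed).
#' @return A list with `ratings` (integer matrix, panelists x scenarios) and
#'   `latent_p` (the scenario probabilities actually used).
#' @export
simulate_scenario_ratings <- function(scenarios, model, n_panelists = 10,
                                      seed = NULL) {
  stopifnot(inherits(model, "generating_model"),
            n_panelists >= 1)
  n_panelists <- as.integer(n_panelists)
  seed <- seed %||% model$seed
  p <- scenario_probabilities(scenarios, model, seed = seed)
  n <- length(p)
  ratings <- with_rng(if (is.null(seed)) NULL else stage_seed(seed, "panel_ratings"), {
    eps <- matrix(stats::rnorm(n_panelists * n, 0, model$rating_noise_sd),
                  n_panelists, n)
    noisy <- rep(p, each = n_panelists) + eps
    m <- clamp_likert(findInterval(noisy, model$cutpoints) + 1L)
    matrix(m, n_panelists, n)
  })
  ids <- as.character(scenarios$scenario_id %||% seq_len(n))
  dimnames(ratings) <- list(paste0("panelist_", seq_len(n_panelists)), ids)
  list(ratings = ratings, latent_p = stats::setNames(p, ids))
}

#' Binary complexity outcomes drawn from the generating truth
#'
#' Direct dichotomization of the generative probabilities: each scenario's
#' outcome is a Bernoulli draw with its latent probability. This is the
#' outcome process under which the logistic model is correctly specified,
#' and the basis of the parameter-recovery validation.
#'
#' @inheritParams simulate_scenario_ratings
#' @return A list with `outcome` (integer 0/1 vector) and `latent_p`.
#' @export
simulate_outcomes <- function(scenarios, model, seed = NULL) {
  stopifnot(inherits(model, "generating_model"))
  seed <- seed %||% model$seed
  p <- scenario_probabilities(scenarios, model, seed = seed)
  y <- with_rng(if (is.null(seed)) NULL else stage_seed(seed, "outcomes"),
                stats::rbinom(length(p), 1L, p))
  ids <- as.character(scenarios$scenario_id %||% seq_along(p))
  list(outcome = stats::setNames(as.integer(y), ids),
       latent_p = stats::setNames(p, ids))
}
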