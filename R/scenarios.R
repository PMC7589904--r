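# Random clinical vignettes: one item per domain drawn from the catalog,
# screened by clinical-consistency rules, with a 2:1 male:female case mix;
# and the consensus rule that classifies panel-rated scenarios.

#' A clinical consistency rule
#'
#' A named predicate on `(sex, selections)` that returns `TRUE` when the
#' combination is clinically admissible. Draws violating any rule are
#' rejected and resampled.
#'
#' @param name Rule name.
#' @param predicate `function(sex, selections)` returning a single logical;
#'   `selections` is a named character vector, domain -> item id.
#' @return A list of class `"consistency_rule"`.
#' @export
consistency_rule <- function(name, predicate) {
  stopifnot(is.character(name), is.function(predicate))
  structure(list(name = name, predicate = predicate),
            class = "consistency_rule")
}

#' Default clinical consistency rules
#'
#' Two sex-specific rules: female scenarios cannot carry prostate-related
#' items (prostate volume, median lobe, prostatic urethra, radical
#' prostatectomy), and male scenarios cannot carry genital prolapse or
#' cystocele.
#'
#' @return List of [consistency_rule()] objects.
#' @export
default_consistency_rules <- function() {
  prostate_items <- c("his_radical_prostatectomy", "acc_large_median_lobe",
                      "acc_large_prostate", "acc_very_large_prostate",
                      "loc_prostatic_urethra")
  list(
    consistency_rule("female_no_prostate_items", function(sex, selections) {
      sex != "female" || !any(selections %in% prostate_items)
    }),
    consistency_rule("male_no_prolapse", function(sex, selections) {
      sex != "male" || !any(selections == "acc_prolapse")
    })
  )
}

#' Split n into sex counts by largest-remainder rounding
#' @noRd
sex_counts <- function(n, sex_ratio) {
  stopifnot(length(sex_ratio) == 2L, all(sex_ratio > 0))
  exact <- n * sex_ratio / sum(sex_ratio)
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), c("male", "female"))
}

#' Generate random clinical scenarios
#'
#' Draws `n` scenarios from the catalog: one item per domain (the five
#' predictor domains are scored with the item's Median Opinion; the
#' descriptor domains are carried for realism but unscored), a sex assigned
#' by `sex_ratio` with largest-remainder rounding, and an age band. Items are
#' drawn with probability proportional to their catalog `frequency` (uniform
#' when frequencies are all 1); draws that violate a consistency rule are
#' rejected and resampled, up to `max_attempts` per scenario.
#'
#' @param catalog A [item_catalog()] with at least one item per predictor
#'   domain.
#' @param n Number of scenarios (>= 1).
#' @param sex_ratio Integer pair `c(male, female)`; default `c(2, 1)`, the
#'   epidemiological male excess of bladder cancer.
#' @param rules List of [consistency_rule()] objects; default
#'   [default_consistency_rules()].
#' @param seed Integer seed or `NULL`.
#' @param age_bands Character vector of age bands sampled uniformly.
#' @param max_attempts Rejection-sampling cap per scenario.
#' @return Data frame, one row per scenario: `scenario_id`, `sex`,
#'   `age_band`, one item-id column per domain, and `score_<domain>` columns
#'   for the predictor domains.
#' @export
#' @examples
#' sc <- generate_scenarios(default_catalog(), 6, seed = 1)
#' table(sc$sex)
generate_scenarios <- function(catalog, n, sex_ratio = c(2, 1),
                               rules = default_consistency_rules(),
                               seed = NULL,
                               age_bands = c("40-59", "60-74", "75+"),
                               max_attempts = 1000) {
  stopifnot(inherits(catalog, "bcc_catalog"), n >= 1)
  n <- as.integer(n)
  domains <- c(PREDICTOR_DOMAINS,
               intersect(DESCRIPTOR_DOMAINS, unique(catalog$domain)))
  pool <- lapply(domains, function(d) catalog_items(catalog, d))
  names(pool) <- domains
  empty <- domains[vapply(pool, nrow, 0L) == 0L]
  if (length(intersect(empty, PREDICTOR_DOMAINS))) {
    stop_bccs("catalog has no items for predictor domain(s): %s",
              paste(intersect(empty, PREDICTOR_DOMAINS), collapse = ", "))
  }
  sexes <- rep(c("male", "female"), sex_counts(n, sex_ratio))
  with_rng(seed, {
    sexes <- sample(sexes)  # interleave
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        sel <- vapply(pool, function(p) {
          p$item_id[sample.int(nrow(p), 1L, prob = p$frequency)]
        }, "")
        ok <- all(vapply(rules, function(r) isTRUE(r$predicate(sexes[i], sel)),
                         TRUE))
        if (ok) break
      }
      if (!ok) {
        stop_bccs("could not draw a rule-consistent scenario for sex '%s' after %d attempts",
                  sexes[i], max_attempts)
      }
      rows[[i]] <- sel
    }
    sel_mat <- do.call(rbind, rows)
    scores <- vapply(PREDICTOR_DOMAINS,
                     function(d) catalog_mo(catalog, sel_mat[, d]),
                     integer(n))
    scores <- matrix(scores, nrow = n,
                     dimnames = list(NULL, PREDICTOR_DOMAINS))
    out <- data.frame(scenario_id = sprintf("scn_%03d", seq_len(n)),
                      sex = sexes,
                      age_band = sample(age_bands, n, replace = TRUE),
                      sel_mat,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (d in PREDICTOR_DOMAINS) out[[paste0("score_", d)]] <- scores[, d]
    rownames(out) <- NULL
    out
  })
}

#' Classify a panel-rated scenario
#'
#' Applies the scenario consensus rule to the panel's ratings: the scenario
#' is `not_complex` when the 95% interval's upper bound is at most
#' "unlikely" (2), `complex` when its lower bound is at least "may
#' occasionally" (3), and `inconclusive` otherwise.
#'
#' @param ratings Integer Likert ratings (1..5), length >= 2.
#' @param ci_method Interval method, see [median_ci()].
#' @return One of `"not_complex"`, `"complex"`, `"inconclusive"`.
#' @export
#' @examples
#' classify_scenario(c(3, 3, 4, 4, 4, 4, 4, 5, 5, 5))  # "complex"
classify_scenario <- function(ratings,
                              ci_method = c("order_statistic", "percentile")) {
  ci_method <- match.arg(ci_method)
  if (length(ratings) < 2L) {
    stop_bccs("at least 2 ratings are required to classify a scenario")
  }
  check_likert_values(ratings, "rating")
  ci <- median_ci(ratings, ci_method)
  if (ci[2] <= 2) "not_complex" else if (ci[1] >= 3) "complex" else "inconclusive"
}

#' Classify and dichotomize a matrix of scenario ratings
#'
#' Applies [classify_scenario()] per column and maps the conclusive classes
#' to a binary outcome (`not_complex` -> 0, `complex` -> 1); inconclusive
#' scenarios carry `NA` and are dropped from modelling.
#'
#' @param ratings Integer matrix, panelists x scenarios.
#' @inheritParams classify_scenario
#' @return Data frame with `scenario_id`, `class` and `outcome` (0/1/NA).
#' @export
dichotomize_scenarios <- function(ratings,
                                  ci_method = c("order_statistic", "percentile")) {
  ci_method <- match.arg(ci_method)
  ratings <- as_response_matrix(ratings)
  cls <- apply(ratings, 2, classify_scenario, ci_method = ci_method)
  data.frame(scenario_id = colnames(ratings),
             class = cls,
             outcome = ifelse(cls == "complex", 1L,
                              ifelse(cls == "not_complex", 0L, NA_integer_)),
             stringsAsFactors = FALSE, row.names = NULL)
}
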