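# End-to-end driver: panel simulation (or file input), Delphi aggregation,
# scenario construction and rating, univariate screen, logistic fit,
# checklist derivation, BCCS scoring, and validation. Every source of
# randomness derives from the single config seed via named stage substreams.

#' Pipeline configuration
#'
#' Defaults reproduce the study design: a 10-member panel, 150 scenarios
#' with a 2:1 male:female mix, a p < 0.1 univariate entry rule, and
#' order-statistic consensus intervals.
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param panel_size Number of panelists.
#' @param n_scenarios Number of scenarios.
#' @param sex_ratio Integer pair `c(male, female)`.
#' @param alpha_screen Univariate entry threshold.
#' @param ci_method Consensus interval method, see [median_ci()].
#' @param granularity_map Checklist rounding steps per domain.
#' @param noise_sd,convergence Panel noise model, see [panel_noise_model()].
#' @param rating_noise_sd,scenario_scale Scenario rating generator, see
#'   [generating_model()].
#' @param synthetic Simulate panel responses and ratings (`TRUE`) or read
#'   them from `paths` (`FALSE`).
#' @param paths Named list of input paths (`catalog`, and for non-synthetic
#'   runs `responses` and `ratings`).
#' @param out_dir Directory for run artifacts, or `NULL` to keep everything
#'   in memory.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, panel_size = 10L, n_scenarios = 150L,
                            sex_ratio = c(2, 1), alpha_screen = 0.1,
                            ci_method = c("order_statistic", "percentile"),
                            granularity_map = default_granularity_map(),
                            noise_sd = 1.4, convergence = 0.7,
                            rating_noise_sd = 0.10, scenario_scale = 1.0,
                            synthetic = TRUE, paths = list(),
                            out_dir = NULL) {
  ci_method <- match.arg(ci_method)
  stopifnot(panel_size >= 2, n_scenarios >= 1)
  structure(list(seed = as.integer(seed), panel_size = as.integer(panel_size),
                 n_scenarios = as.integer(n_scenarios), sex_ratio = sex_ratio,
                 alpha_screen = alpha_screen, ci_method = ci_method,
                 granularity_map = granularity_map, noise_sd = noise_sd,
                 convergence = convergence,
                 rating_noise_sd = rating_noise_sd,
                 scenario_scale = scenario_scale,
                 synthetic = isTRUE(synthetic), paths = paths,
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_bccs("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full complexity pipeline
#'
#' Executes every stage end to end and returns the run artifacts; with
#' `out_dir` set, also writes them as CSV/JSON together with a JSON manifest
#' recording each stage, its parameters and the MD5 of each artifact file.
#' Runs are deterministic under a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"bcc_run"` with elements `catalog`, `responses`
#'   (rounds 1 and 2), `item_summaries`, `consensus`, `scenarios`,
#'   `ratings`, `classes`, `screen`, `screened_domains`, `model`,
#'   `checklist`, `bccs`, `validation` and `manifest`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(seed = 1, n_scenarios = 60))
#' run$validation$comparison
#' }
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  manifest <- list(package = "bccs",
                   version = as.character(utils::packageVersion("bccs")),
                   config = config[setdiff(names(config),
                                           c("paths", "out_dir"))],
                   stages = list(), files = list())

  catalog <- run_stage("catalog", {
    if (!is.null(config$paths$catalog)) {
      read_item_catalog(config$paths$catalog)
    } else if (config$synthetic) {
      default_catalog()
    } else {
      stop_bccs("non-synthetic mode requires a catalog path")
    }
  })
  manifest$stages$catalog <- list(n_items = nrow(catalog))

  noise <- panel_noise_model(config$noise_sd, config$convergence,
                             seed = stage_seed(seed, "panel_round1"))
  responses <- run_stage("simulate-panel", {
    if (config$synthetic) {
      truths <- data.frame(item_id = catalog$item_id,
                           latent_complexity = catalog$median_opinion,
                           stringsAsFactors = FALSE)
      r1 <- simulate_item_responses(truths, config$panel_size, noise)
      list(round1 = r1, round2 = simulate_round2(r1, noise))
    } else {
      if (is.null(config$paths$responses)) {
        stop_bccs("non-synthetic mode requires a panel response path")
      }
      r <- read_panel_responses(config$paths$responses)
      list(round1 = r, round2 = r)
    }
  })
  manifest$stages$simulate_panel <- list(panel_size = nrow(responses$round2),
                                         n_items = ncol(responses$round2))

  summaries <- run_stage("summarize", {
    lapply(responses, summarize_panel, ci_method = config$ci_method)
  })
  consensus <- lapply(summaries, consensus_rate)
  manifest$stages$summarize <-
    list(consensus_round1 = consensus$round1$fraction,
         consensus_round2 = consensus$round2$fraction)

  scenarios <- run_stage("generate-scenarios", {
    generate_scenarios(catalog, config$n_scenarios, config$sex_ratio,
                       seed = stage_seed(seed, "scenarios"))
  })
  manifest$stages$generate_scenarios <-
    list(n = nrow(scenarios), male = sum(scenarios$sex == "male"),
         female = sum(scenarios$sex == "female"))

  gm <- published_generating_model(rating_noise_sd = config$rating_noise_sd,
                                   scenario_scale = config$scenario_scale,
                                   seed = stage_seed(seed, "ratings"))
  ratings <- run_stage("rate-scenarios", {
    if (config$synthetic) {
      simulate_scenario_ratings(scenarios, gm, config$panel_size)$ratings
    } else {
      if (is.null(config$paths$ratings)) {
        stop_bccs("non-synthetic mode requires a scenario rating path")
      }
      read_panel_responses(config$paths$ratings)
    }
  })
  classes <- run_stage("classify", {
    dichotomize_scenarios(ratings, config$ci_method)
  })
  keep <- !is.na(classes$outcome)
  manifest$stages$classify <- list(conclusive = sum(keep),
                                   complex = sum(classes$outcome[keep]))

  sc_keep <- scenarios[match(classes$scenario_id[keep],
                             scenarios$scenario_id), , drop = FALSE]
  y <- classes$outcome[keep]
  smat <- scenario_scores(sc_keep, PREDICTOR_DOMAINS)

  screen <- run_stage("screen", screen_scores(smat, y))
  screened <- screen_domains(stats::setNames(screen$p_value, screen$domain),
                             config$alpha_screen)
  manifest$stages$screen <- list(retained = screened)

  model <- run_stage("fit", fit_complexity(smat[, screened, drop = FALSE], y))
  manifest$stages$fit <- list(n_obs = model$n_obs,
                              converged = model$converged)

  checklist <- run_stage("derive-checklist", {
    derive_checklist(model, catalog,
                     config$granularity_map[names(model$coefficients)])
  })
  bccs <- run_stage("score-case", score_scenarios(checklist, sc_keep))

  validation <- run_stage("validate", {
    p_model <- predict(model, type = "response")
    roc_model <- roc_auc(p_model, y)
    roc_bccs <- roc_auc(bccs, y)
    list(roc_model = roc_model, roc_bccs = roc_bccs,
         comparison = compare_auc(p_model, bccs, y),
         calibration = calibration_metrics(p_model, y),
         predictive = predictive_values(bccs, y,
                                        sort(unique(round(bccs)))))
  })
  manifest$stages$validate <-
    list(auc_model = validation$roc_model$auc,
         auc_bccs = validation$roc_bccs$auc,
         auc_comparison_p = validation$comparison$p_value,
         calibration_slope = validation$calibration$slope,
         citl = validation$calibration$citl)

  run <- list(catalog = catalog, responses = responses,
              item_summaries = summaries, consensus = consensus,
              scenarios = scenarios, ratings = ratings, classes = classes,
              screen = screen, screened_domains = screened, model = model,
              checklist = checklist, bccs = bccs, validation = validation)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$out_dir, f)
    write_panel_responses(responses$round2, pth("panel_round2.csv"))
    write_item_summaries(summaries$round2, pth("item_summaries.csv"))
    write_scenarios(scenarios, pth("scenarios.csv"))
    write_panel_responses(ratings, pth("scenario_ratings.csv"))
    utils::write.csv(classes, pth("scenario_classes.csv"), row.names = FALSE)
    write_model(model, pth("model.json"))
    write_checklist(checklist, pth("checklist.csv"))
    utils::write.csv(data.frame(scenario_id = names(bccs), bccs = bccs),
                     pth("bccs.csv"), row.names = FALSE)
    jsonlite::write_json(manifest$stages$validate, pth("validation.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c("panel_round2.csv", "item_summaries.csv", "scenarios.csv",
               "scenario_ratings.csv", "scenario_classes.csv", "model.json",
               "checklist.csv", "bccs.csv", "validation.json")
    manifest$files <- as.list(stats::setNames(
      unname(tools::md5sum(vapply(files, pth, ""))), files))
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  run$manifest <- manifest
  class(run) <- "bcc_run"
  run
}

#' @export
print.bcc_run <- function(x, ...) {
  st <- x$manifest$stages
  cat("Complexity pipeline run\n")
  cat(sprintf("  items rated: %d; consensus round 1 %.2f, round 2 %.2f\n",
              st$simulate_panel$n_items, st$summarize$consensus_round1,
              st$summarize$consensus_round2))
  cat(sprintf("  scenarios: %d (%d male / %d female), %d conclusive, %d complex\n",
              st$generate_scenarios$n, st$generate_scenarios$male,
              st$generate_scenarios$female, st$classify$conclusive,
              st$classify$complex))
  cat(sprintf("  model AUC %.3f, BCCS AUC %.3f (paired p = %.2f); slope %.3f, CITL %.3f\n",
              st$validate$auc_model, st$validate$auc_bccs,
              st$validate$auc_comparison_p, st$validate$calibration_slope,
              st$validate$citl))
  invisible(x)
}
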