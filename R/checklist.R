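# The Bladder Complexity Checklist: per-item weight-adjusted scores
# (regression coefficient x Median Opinion, rounded for bedside use) and the
# Bladder Complexity Checklist Sum (BCCS) over the five predictor domains.

#' Weight-adjusted score of one checklist item
#'
#' The product of a domain's regression coefficient and an item's Median
#' Opinion, rounded to the nearest multiple of `granularity` with ties
#' rounded up.
#'
#' @param coefficient Positive regression coefficient.
#' @param median_opinion Integer Median Opinion, 1..5.
#' @param granularity Rounding step, 0.5 or 1.0.
#' @return The rounded weight.
#' @export
#' @examples
#' weight_adjusted_score(1.44, 3, 0.5)  # 4.5
weight_adjusted_score <- function(coefficient, median_opinion,
                                  granularity = 1.0) {
  if (any(coefficient <= 0)) {
    stop_bccs("coefficient must be positive, got %s",
              format(coefficient[coefficient <= 0][1L]))
  }
  check_likert_values(median_opinion, "median opinion")
  stopifnot(granularity %in% c(0.5, 1.0))
  floor(coefficient * median_opinion / granularity + 0.5) * granularity
}

default_granularity_map <- function() {
  g <- stats::setNames(rep(1.0, length(PREDICTOR_DOMAINS)), PREDICTOR_DOMAINS)
  g["location"] <- 0.5
  g
}

new_checklist <- function(rows, provenance) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  stopifnot(all(c("domain", "item_id", "label", "weight") %in% names(rows)))
  miss <- setdiff(PREDICTOR_DOMAINS, rows$domain)
  if (length(miss)) {
    stop_bccs("checklist lacks predictor domain(s): %s",
              paste(miss, collapse = ", "))
  }
  if (any(rows$weight <= 0)) stop_bccs("checklist weights must be positive")
  if (any(abs(rows$weight * 2 - round(rows$weight * 2)) > 1e-9)) {
    stop_bccs("checklist weights must be multiples of 0.5")
  }
  rownames(rows) <- NULL
  structure(rows, class = c("bcc_checklist", "data.frame"),
            provenance = provenance)
}

#' Derive a checklist from a model and an item catalog
#'
#' One row per predictor-domain catalog item, with weight
#' `weight_adjusted_score(coef[domain], MO[item], granularity[domain])`.
#' The default granularity map rounds the location domain to halves and the
#' others to integers, which reproduces every published checklist weight
#' (no single rounding rule does: 1.44 x 3 prints as 4.5 but 1.10 x 3 as 3).
#'
#' @param model A `"bcc_model"`.
#' @param catalog A [item_catalog()] with Median Opinions for every
#'   predictor-domain item.
#' @param granularity_map Named numeric vector, domain -> rounding step.
#' @return A `"bcc_checklist"` data frame with provenance `"derived"`.
#' @export
#' @examples
#' derive_checklist(published_model(), default_catalog())
derive_checklist <- function(model, catalog,
                             granularity_map = default_granularity_map()) {
  stopifnot(inherits(model, "bcc_model"), inherits(catalog, "bcc_catalog"))
  domains <- names(model$coefficients)
  miss <- setdiff(domains, names(granularity_map))
  if (length(miss)) {
    stop_bccs("granularity map lacks domain(s): %s", paste(miss, collapse = ", "))
  }
  rows <- do.call(rbind, lapply(domains, function(d) {
    it <- catalog_items(catalog, d)
    if (!nrow(it)) stop_bccs("catalog has no items for domain '%s'", d)
    if (anyNA(it$median_opinion)) {
      stop_bccs("missing Median Opinion for item(s): %s",
                paste(it$item_id[is.na(it$median_opinion)], collapse = ", "))
    }
    data.frame(domain = d, item_id = it$item_id, label = it$label,
               weight = weight_adjusted_score(model$coefficients[[d]],
                                              it$median_opinion,
                                              granularity_map[[d]]),
               stringsAsFactors = FALSE)
  }))
  new_checklist(rows, "derived")
}

#' The published checklist
#'
#' Loads the packaged transcription of the published five-domain checklist
#' (weight-adjusted scores per item). Note the dome-row companions
#' "Anticipate obturator jerk" and "Diverticulum" are recorded under the
#' location domain; their domain assignment is ambiguous in the published
#' layout.
#'
#' @return A `"bcc_checklist"` with provenance `"published_table3"`.
#' @export
published_checklist <- function() {
  rows <- utils::read.csv(system.file("extdata", "table3_checklist.csv",
                                      package = "bccs", mustWork = TRUE),
                          stringsAsFactors = FALSE)
  new_checklist(rows, "published_table3")
}

#' @export
print.bcc_checklist <- function(x, ...) {
  cat(sprintf("Bladder Complexity Checklist (%s): %d items\n",
              attr(x, "provenance"), nrow(x)))
  for (d in intersect(PREDICTOR_DOMAINS, unique(x$domain))) {
    rows <- x[x$domain == d, ]
    cat(sprintf("  %-9s %s\n", d,
                paste(sprintf("%s (%g)", rows$item_id, rows$weight),
                      collapse = ", ")))
  }
  invisible(x)
}

resolve_checklist_item <- function(checklist, domain, key) {
  rows <- checklist[checklist$domain == domain, , drop = FALSE]
  if (!nrow(rows)) stop_bccs("checklist has no domain '%s'", domain)
  i <- match(key, rows$item_id)
  if (is.na(i)) i <- match(tolower(key), tolower(rows$label))
  if (is.na(i)) {
    stop_bccs("unknown item '%s' in domain '%s'", key, domain)
  }
  rows[i, , drop = FALSE]
}

#' Bladder Complexity Checklist Sum for one case
#'
#' Sums the weights of the selected item in each of the five predictor
#' domains. Items may be given by id or by their checklist label
#' (case-insensitive exact match).
#'
#' @param checklist A `"bcc_checklist"`.
#' @param case Named list or character vector: domain -> item id or label,
#'   covering all five predictor domains.
#' @return An object of class `"bccs_score"`: list with `value` (the BCCS)
#'   and `components` (named per-domain weights).
#' @export
#' @examples
#' score_case(published_checklist(),
#'   c(history = "No relevant history", access = "Thin bladder wall",
#'     number = "1-3 tumours", size = "3-5 cm", location = "Dome"))
score_case <- function(checklist, case) {
  stopifnot(inherits(checklist, "bcc_checklist"))
  case <- unlist(case)
  miss <- setdiff(PREDICTOR_DOMAINS, names(case))
  if (length(miss)) {
    stop_bccs("case lacks domain(s): %s", paste(miss, collapse = ", "))
  }
  comp <- vapply(PREDICTOR_DOMAINS, function(d) {
    resolve_checklist_item(checklist, d, case[[d]])$weight
  }, 0)
  structure(list(value = sum(comp), components = comp,
                 selections = case[PREDICTOR_DOMAINS]),
            class = "bccs_score")
}

#' @export
print.bccs_score <- function(x, ...) {
  cat(sprintf("BCCS = %g\n", x$value))
  for (d in names(x$components)) {
    cat(sprintf("  %-9s %-28s %g\n", d, x$selections[[d]], x$components[[d]]))
  }
  invisible(x)
}

#' BCCS for every scenario of a scenario table
#'
#' @param checklist A `"bcc_checklist"`.
#' @param scenarios Scenario data frame from [generate_scenarios()].
#' @return Numeric vector of sums, named by scenario id.
#' @export
score_scenarios <- function(checklist, scenarios) {
  stopifnot(inherits(checklist, "bcc_checklist"))
  w <- stats::setNames(checklist$weight, checklist$item_id)
  miss <- setdiff(PREDICTOR_DOMAINS, names(scenarios))
  if (length(miss)) {
    stop_bccs("scenarios lack selection column(s): %s",
              paste(miss, collapse = ", "))
  }
  parts <- vapply(PREDICTOR_DOMAINS, function(d) {
    wi <- w[scenarios[[d]]]
    if (anyNA(wi)) {
      stop_bccs("scenario item '%s' is not in the checklist",
                scenarios[[d]][which(is.na(wi))[1L]])
    }
    unname(wi)
  }, numeric(nrow(scenarios)))
  sums <- rowSums(matrix(parts, nrow = nrow(scenarios)))
  stats::setNames(sums, scenarios$scenario_id)
}

#' Write a checklist to CSV
#'
#' @param checklist A `"bcc_checklist"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(checklist, path) {
  utils::write.csv(as.data.frame(checklist), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
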