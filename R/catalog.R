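# The item catalog: risk items grouped into domains, each carrying the
# panel's Median Opinion and, for the five predictor domains, the published
# checklist weight. Catalogs are plain data frames of class "bcc_catalog".

CATALOG_DOMAINS <- c(PREDICTOR_DOMAINS, "patient_characteristics",
                     DESCRIPTOR_DOMAINS, "environment")

#' Construct and validate an item catalog
#'
#' @param items Data frame with columns `item_id`, `domain`, `label`,
#'   `median_opinion` (integer 1..5) and optionally `weight` (published
#'   checklist weight, positive) and `frequency` (relative sampling weight
#'   used by [generate_scenarios()]; defaults to 1).
#' @return The validated catalog, classed `"bcc_catalog"`.
#' @export
item_catalog <- function(items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  need <- c("item_id", "domain", "label", "median_opinion")
  miss <- setdiff(need, names(items))
  if (length(miss)) {
    stop_bccs("catalog lacks columns: %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(items$item_id)) {
    stop_bccs("duplicated item_id in catalog: %s",
              items$item_id[duplicated(items$item_id)][1L])
  }
  bad <- !items$domain %in% CATALOG_DOMAINS
  if (any(bad)) {
    stop_bccs("unknown domain '%s' for item '%s'",
              items$domain[bad][1L], items$item_id[bad][1L])
  }
  check_likert_values(items$median_opinion, "median opinion")
  if (!"weight" %in% names(items)) items$weight <- NA_real_
  w <- items$weight[!is.na(items$weight)]
  if (any(w <= 0)) stop_bccs("catalog weights must be positive")
  if (!"frequency" %in% names(items)) items$frequency <- 1
  items$frequency[is.na(items$frequency)] <- 1
  if (any(items$frequency <= 0)) stop_bccs("catalog frequencies must be positive")
  class(items) <- c("bcc_catalog", "data.frame")
  items
}

#' Read an item catalog from CSV
#'
#' @param path CSV with the columns described in [item_catalog()].
#' @return A `"bcc_catalog"` data frame.
#' @export
read_item_catalog <- function(path) {
  item_catalog(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The packaged item catalog
#'
#' Items of the five predictor domains transcribe the published checklist
#' (ids, labels and weights), with Median Opinions backed out of the
#' weight-adjusted scores. The unscored descriptor domains (tumour structure,
#' bladder anatomy) are synthetic stand-ins: the study's figure-level item
#' lists are not machine-readable, so clinically plausible items are supplied
#' in their place. Sampling frequencies favour the baseline
#' ("no relevant findings") item of each predictor domain, emulating a
#' realistic case mix.
#'
#' @return A `"bcc_catalog"` data frame.
#' @export
#' @examples
#' head(default_catalog())
default_catalog <- function() {
  read_item_catalog(system.file("extdata", "item_catalog_synthetic.csv",
                                package = "bccs", mustWork = TRUE))
}

#' @export
print.bcc_catalog <- function(x, ...) {
  cat(sprintf("Item catalog: %d items in %d domains\n", nrow(x),
              length(unique(x$domain))))
  tab <- table(factor(x$domain, levels = intersect(CATALOG_DOMAINS, x$domain)))
  for (d in names(tab)) cat(sprintf("  %-22s %d items\n", d, tab[[d]]))
  invisible(x)
}

catalog_items <- function(catalog, domain) {
  catalog[catalog$domain == domain, , drop = FALSE]
}

catalog_mo <- function(catalog, item_id) {
  i <- match(item_id, catalog$item_id)
  if (anyNA(i)) {
    stop_bccs("unknown catalog item '%s'", item_id[which(is.na(i))[1L]])
  }
  catalog$median_opinion[i]
}
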