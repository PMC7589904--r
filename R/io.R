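# CSV interchange: panel response / scenario rating matrices, item catalogs,
# scenario tables. Comma-separated, UTF-8, header row required, "." decimal.

as_response_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("item_", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("panelist_", seq_len(nrow(m)))
  storage.mode(m) <- "integer"
  m
}

#' Read a panel response (or scenario rating) matrix
#'
#' The file holds panelists in rows and items (or scenarios) in columns;
#' the first column, `panelist`, carries the panelist identifier. Every cell
#' must be an integer Likert score in 1..5; offending cells are reported by
#' row and column.
#'
#' @param path CSV file path.
#' @return Integer matrix with panelist row names and item column names.
#' @export
read_panel_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2L) stop_bccs("'%s' holds no responses", path)
  if (names(df)[1L] != "panelist") {
    stop_bccs("first column of '%s' must be 'panelist', found '%s'",
              path, names(df)[1L])
  }
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- !is.finite(v) | v != round(v) | v < 1 | v > 5
    if (any(bad)) {
      i <- which(bad)[1L]
      stop_bccs("invalid response '%s' at row %d (panelist '%s'), column '%s': must be an integer in 1..5",
                as.character(m[i, j]), i, ids[i], colnames(m)[j])
    }
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  # stable column order so files with permuted columns compare equal
  m[, order(colnames(m)), drop = FALSE]
}

#' Write a panel response matrix
#'
#' @param responses Integer matrix (panelists x items).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_responses <- function(responses, path) {
  responses <- as_response_matrix(responses)
  df <- data.frame(panelist = rownames(responses), responses,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-item Delphi summaries
#'
#' @param summaries Data frame from [summarize_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_item_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scenario table
#'
#' One row per scenario: `scenario_id`, `sex`, `age_band`, one item-id column
#' per domain, and one `score_<domain>` column per predictor domain.
#'
#' @param scenarios Scenario data frame from [generate_scenarios()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  utils::write.csv(scenarios, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario table written by [write_scenarios()]
#'
#' @param path CSV file path.
#' @return Scenario data frame.
#' @export
read_scenarios <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("scenario_id", "sex", "age_band", PREDICTOR_DOMAINS,
            paste0("score_", PREDICTOR_DOMAINS))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_bccs("scenario file '%s' lacks columns: %s", path,
              paste(miss, collapse = ", "))
  }
  df
}
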