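# Aggregation of expert Likert panels: median opinion, 95% interval for the
# median, and the consensus rule (interval bounded within two consecutive
# scores).

#' Distribution-free 95% interval for the median of Likert scores
#'
#' `order_statistic` gives the exact binomial order-statistic interval for
#' the population median at >= 95% nominal coverage: the interval
#' \eqn{(x_{(k)}, x_{(n+1-k)})} with the largest `k` such that
#' \eqn{P(\mathrm{Bin}(n, 1/2) \le k - 1) \le 0.025}. For very small panels
#' (n < 6) no such interval reaches 95% coverage and the sample range is
#' returned. `percentile` gives the empirical 2.5 and 97.5 percentiles
#' (type-7 linear interpolation).
#'
#' @param scores Numeric vector of Likert scores (integers 1..5).
#' @param ci_method `"order_statistic"` (default) or `"percentile"`.
#' @return Numeric length-2 vector `c(low, high)`.
#' @export
#' @examples
#' median_ci(c(3, 3, 3, 3, 3, 4, 4, 4, 4, 4))
median_ci <- function(scores, ci_method = c("order_statistic", "percentile")) {
  ci_method <- match.arg(ci_method)
  n <- length(scores)
  if (n < 2L) stop_bccs("at least 2 scores are required, got %d", n)
  if (ci_method == "percentile") {
    return(unname(stats::quantile(scores, c(0.025, 0.975), type = 7)))
  }
  s <- sort(scores)
  kcand <- seq_len(max(floor(n / 2), 1))
  valid <- stats::pbinom(kcand - 1, n, 0.5) <= 0.025
  k <- if (any(valid)) max(kcand[valid]) else 1L
  c(s[k], s[n + 1L - k])
}

#' Summarize one Delphi item
#'
#' Computes the Median Opinion (MO), a 95% interval for the median, and the
#' consensus flag: consensus holds when the interval is bounded within two
#' consecutive Likert scores. With an even panel the sample median can fall
#' on a half-integer; by default it is rounded up, i.e. toward higher
#' complexity.
#'
#' @param scores Integer Likert scores (1..5), length >= 2.
#' @param ci_method Interval method, see [median_ci()].
#' @param item_id Optional identifier carried into the result.
#' @param half Rounding of half-integer medians: `"up"` (default) or `"down"`.
#' @return A one-row data frame with columns `item_id`, `median_opinion`,
#'   `ci_low`, `ci_high`, `consensus`, `n_responses`.
#' @export
#' @examples
#' summarize_item(c(3, 3, 3, 3, 3, 4, 4, 4, 4, 4))  # MO 4, CI (3, 4), consensus
summarize_item <- function(scores, ci_method = c("order_statistic", "percentile"),
                           item_id = NA_character_, half = c("up", "down")) {
  ci_method <- match.arg(ci_method)
  half <- match.arg(half)
  if (length(scores) < 2L) {
    stop_bccs("at least 2 scores are required to summarize an item, got %d",
              length(scores))
  }
  check_likert_values(scores, "Likert score")
  m <- stats::median(scores)
  mo <- if (m == round(m)) as.integer(m) else {
    if (half == "up") as.integer(ceiling(m)) else as.integer(floor(m))
  }
  ci <- median_ci(scores, ci_method)
  # consensus: the interval fits inside [k, k + 1] for some integer k
  consensus <- ci[2] <= floor(ci[1]) + 1
  data.frame(item_id = item_id, median_opinion = mo,
             ci_low = ci[1], ci_high = ci[2],
             consensus = consensus, n_responses = length(scores),
             stringsAsFactors = FALSE)
}

#' Summarize every item of a panel response matrix
#'
#' @param responses Integer matrix, panelists in rows, items in columns
#'   (column names are the item ids).
#' @inheritParams summarize_item
#' @return Data frame with one row per item, as in [summarize_item()].
#' @export
summarize_panel <- function(responses, ci_method = c("order_statistic", "percentile"),
                            half = c("up", "down")) {
  ci_method <- match.arg(ci_method)
  half <- match.arg(half)
  responses <- as_response_matrix(responses)
  out <- do.call(rbind, lapply(seq_len(ncol(responses)), function(j) {
    summarize_item(responses[, j], ci_method, item_id = colnames(responses)[j],
                   half = half)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of items reaching consensus
#'
#' @param summaries Data frame of item summaries as returned by
#'   [summarize_panel()].
#' @return A list with `fraction`, `consensual_ids` and `non_consensual_ids`.
#' @export
consensus_rate <- function(summaries) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    stop_bccs("'summaries' must be a non-empty data frame of item summaries")
  }
  stopifnot(all(c("item_id", "consensus") %in% names(summaries)))
  yes <- summaries$consensus
  list(fraction = mean(yes),
       consensual_ids = summaries$item_id[yes],
       non_consensual_ids = summaries$item_id[!yes])
}
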