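# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# AUC as the exhaustive concordant-pair count (+ half ties) over all
# positive-negative pairs.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact two-tailed Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups (midranks for ties).
enumerate_mw_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(utils::combn(length(r), nx), 2,
              function(i) sum(r[i]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Order-statistic 95% interval for the median, straight from the binomial
# distribution of the number of observations below the median.
oracle_median_ci <- function(scores) {
  n <- length(scores)
  k <- 0L
  repeat {
    if (stats::pbinom(k, n, 0.5) > 0.025) break
    k <- k + 1L
  }
  # k is now the largest count with lower tail <= 0.025, plus one
  k <- max(k, 1L)
  s <- sort(scores)
  c(s[k], s[n + 1L - k])
}

score_columns <- function(scenarios) {
  m <- as.matrix(scenarios[, paste0("score_", c("history", "access", "number",
                                                "size", "location"))])
  colnames(m) <- sub("^score_", "", colnames(m))
  m
}

# A minimal catalog with one item per Median Opinion level in each
# predictor domain, for exhaustive score-grid checks.
grid_catalog <- function() {
  d <- c("history", "access", "number", "size", "location")
  item_catalog(data.frame(
    item_id = paste0(rep(d, each = 5), "_mo", 1:5),
    domain = rep(d, each = 5),
    label = paste0(rep(d, each = 5), " level ", 1:5),
    median_opinion = rep(1:5, 5),
    stringsAsFactors = FALSE))
}
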