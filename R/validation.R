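# Discrimination and calibration of a complexity score: ROC curve and AUC
# with an asymptotic concordance CI, paired AUC comparison (DeLong
# construction), logistic recalibration (slope, calibration-in-the-large),
# and PPV/NPV threshold sweeps.

check_binary_labels <- function(labels) {
  if (anyNA(labels) || !all(labels %in% 0:1)) {
    stop_bccs("labels must be 0/1 with no missing values")
  }
  if (!any(labels == 0) || !any(labels == 1)) {
    stop_bccs("both classes must be present")
  }
  invisible(TRUE)
}

# DeLong placements: for each positive, the fraction of negatives it beats
# (ties half); and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp),
       auc = mean(cmp))
}

#' ROC curve and AUC of a score against a binary outcome
#'
#' The curve is built from all distinct score thresholds (decreasing); the
#' AUC is the trapezoid area, which equals the tie-adjusted concordance
#' probability. The confidence interval uses the asymptotic variance of the
#' concordance statistic (DeLong components).
#'
#' @param scores Numeric scores; higher means more likely complex.
#' @param labels Binary outcome (0/1), both classes present.
#' @param conf_level Confidence level of the AUC interval.
#' @return Object of class `"bcc_roc"`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `auc_ci`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc  # 1
roc_auc <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels), is.numeric(scores))
  check_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pl <- delong_placements(scores, labels)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * zq * sqrt(v), 0), 1)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = auc_trap, auc_ci = ci, auc_var = v,
                 n_pos = n1, n_neg = n0),
            class = "bcc_roc")
}

#' @export
print.bcc_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.bcc_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Paired comparison of two AUCs (DeLong construction)
#'
#' Tests the difference between the AUCs of two scores measured on the same
#' subjects, using the covariance of their DeLong placement components.
#' Identical rankings give a zero difference and p = 1.
#'
#' @param scores_a,scores_b Numeric scores of equal length.
#' @param labels Binary outcome (0/1).
#' @return `"bcc_stat"` list: `statistic` (z), `p_value`, `auc_a`, `auc_b`,
#'   `method = "delong_paired"`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop_bccs("score vectors differ in length (%d vs %d)",
              length(scores_a), length(scores_b))
  }
  stopifnot(length(labels) == length(scores_a))
  check_binary_labels(labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  v <- stats::var(pa$v10 - pb$v10) / n1 + stats::var(pa$v01 - pb$v01) / n0
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = p, auc_a = pa$auc, auc_b = pb$auc,
                 auc_difference = d, method = "delong_paired"),
            class = "bcc_stat")
}

#' Calibration slope, calibration-in-the-large, and risk bins
#'
#' The calibration slope is the coefficient of the logit of the predicted
#' probabilities in a logistic recalibration fit; calibration-in-the-large
#' (CITL) is the intercept of a logistic fit with the logit entered as a
#' fixed offset (slope constrained to 1). A perfectly calibrated in-sample
#' maximum-likelihood fit has slope 1 and CITL 0. Deciles-of-risk bins are
#' reported for plotting, merging bins with fewer than `min_bin` cases.
#'
#' @param predicted Predicted probabilities, strictly inside (0, 1).
#' @param outcomes Binary outcome (0/1), both classes present.
#' @param n_bins Number of risk bins before merging (default 10).
#' @param min_bin Minimum bin occupancy (default 5).
#' @return Object of class `"bcc_calibration"`: `slope`, `citl`, `bins`
#'   (data frame `mean_predicted`, `observed_fraction`, `n`).
#' @export
calibration_metrics <- function(predicted, outcomes, n_bins = 10, min_bin = 5) {
  stopifnot(length(predicted) == length(outcomes))
  check_binary_labels(outcomes)
  if (any(!is.finite(predicted)) || any(predicted <= 0 | predicted >= 1)) {
    stop_bccs("predicted probabilities must lie strictly inside (0, 1)")
  }
  lp <- stats::qlogis(predicted)
  if (stats::var(lp) <= .Machine$double.eps) {
    stop_bccs("degenerate predictions: zero variance on the logit scale")
  }
  y <- as.integer(outcomes)
  ctl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  slope <- unname(stats::coef(suppressWarnings(
    stats::glm(y ~ lp, family = stats::binomial(), control = ctl)))[2L])
  citl <- unname(stats::coef(suppressWarnings(
    stats::glm(y ~ 1 + offset(lp), family = stats::binomial(),
               control = ctl)))[1L])
  # deciles of predicted risk, merged forward when underpopulated
  br <- unique(stats::quantile(predicted, seq(0, 1, length.out = n_bins + 1)))
  g <- cut(predicted, br, include.lowest = TRUE, labels = FALSE)
  tab <- lapply(sort(unique(g)), function(k) {
    data.frame(mean_predicted = mean(predicted[g == k]),
               observed_fraction = mean(y[g == k]), n = sum(g == k))
  })
  bins <- do.call(rbind, tab)
  while (nrow(bins) > 1L && any(bins$n < min_bin)) {
    k <- which(bins$n < min_bin)[1L]
    j <- if (k == nrow(bins)) k - 1L else k + 1L
    n <- bins$n[k] + bins$n[j]
    bins$mean_predicted[j] <- (bins$mean_predicted[k] * bins$n[k] +
                                 bins$mean_predicted[j] * bins$n[j]) / n
    bins$observed_fraction[j] <- (bins$observed_fraction[k] * bins$n[k] +
                                    bins$observed_fraction[j] * bins$n[j]) / n
    bins$n[j] <- n
    bins <- bins[-k, , drop = FALSE]
  }
  rownames(bins) <- NULL
  structure(list(slope = slope, citl = citl, bins = bins),
            class = "bcc_calibration")
}

#' @export
print.bcc_calibration <- function(x, ...) {
  cat(sprintf("Calibration: slope = %.4f, CITL = %.4f (%d bins)\n",
              x$slope, x$citl, nrow(x$bins)))
  invisible(x)
}

#' @export
plot.bcc_calibration <- function(x, ...) {
  graphics::plot(x$bins$mean_predicted, x$bins$observed_fraction,
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19,
                 xlab = "Mean predicted probability",
                 ylab = "Observed fraction complex",
                 main = sprintf("Calibration (slope %.2f, CITL %.2f)",
                                x$slope, x$citl), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Positive and negative predictive values across thresholds
#'
#' For each threshold `t`: PPV is the fraction of complex cases among
#' `score >= t`, NPV the fraction of non-complex cases among `score < t`.
#' A side with no cases yields `NA` (undefined), never zero.
#'
#' @param scores Numeric scores.
#' @param labels Binary outcome (0/1).
#' @param thresholds Non-empty numeric vector of thresholds.
#' @return Object of class `"bcc_pv"`: data frame with `threshold`, `ppv`,
#'   `npv`, `n_above`, `n_below`.
#' @export
predictive_values <- function(scores, labels, thresholds) {
  if (!length(thresholds)) stop_bccs("'thresholds' must be non-empty")
  stopifnot(length(scores) == length(labels))
  if (anyNA(labels) || !all(labels %in% 0:1)) {
    stop_bccs("labels must be 0/1 with no missing values")
  }
  rows <- do.call(rbind, lapply(sort(thresholds), function(t) {
    up <- scores >= t
    data.frame(threshold = t,
               ppv = if (any(up)) mean(labels[up]) else NA_real_,
               npv = if (any(!up)) mean(1 - labels[!up]) else NA_real_,
               n_above = sum(up), n_below = sum(!up))
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("bcc_pv", "data.frame"))
}

#' @export
plot.bcc_pv <- function(x, ...) {
  graphics::plot(x$threshold, x$ppv, type = "b", col = "red", ylim = c(0, 1),
                 xlab = "Score threshold", ylab = "Predictive value",
                 main = "PPV / NPV by score increment", pch = 19, ...)
  graphics::lines(x$threshold, x$npv, type = "b", col = "blue", pch = 19)
  graphics::legend("bottomright", c("PPV", "NPV"), col = c("red", "blue"),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
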