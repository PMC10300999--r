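# ROC performance statistics: Mann-Whitney AUC, operating-point metrics,
# stratified-bootstrap confidence intervals, unpaired bootstrap AUC
# comparison, and DeLong's paired test.

check_labels <- function(labels) {
  l <- as.integer(as.logical(labels))
  if (any(is.na(l))) stop_readiff("labels must be binary", "readiff_input_error")
  if (length(unique(l)) < 2) {
    stop_readiff("both classes must be present", "readiff_input_error")
  }
  l
}

#' Area under the ROC curve
#'
#' Mann-Whitney U-statistic estimator: the proportion of positive/negative
#' score pairs ranked correctly, with ties given half credit.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (logical or 0/1); 1 = positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  l <- check_labels(labels)
  stopifnot(length(scores) == length(l))
  r <- rank(scores)
  n_pos <- sum(l == 1); n_neg <- sum(l == 0)
  (sum(r[l == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Calls scores `>= threshold` positive.
#'
#' @inheritParams auc
#' @param threshold operating threshold (default 0.5).
#' @return Named vector: `sensitivity`, `specificity`, `accuracy`.
#' @export
operating_metrics <- function(scores, labels, threshold = 0.5) {
  l <- check_labels(labels)
  pos_call <- scores >= threshold
  sens <- mean(pos_call[l == 1])
  spec <- mean(!pos_call[l == 0])
  acc <- mean(pos_call == (l == 1))
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

stratified_boot_aucs <- function(scores, labels, n_boot) {
  l <- check_labels(labels)
  ip <- which(l == 1); im <- which(l == 0)
  vapply(seq_len(n_boot), function(b) {
    i <- c(sample(ip, length(ip), replace = TRUE),
           sample(im, length(im), replace = TRUE))
    auc(scores[i], l[i])
  }, 0)
}

#' Stratified-bootstrap confidence interval for the AUC
#'
#' Positives and negatives are resampled independently with replacement
#' (preserving class sizes) and the percentile interval of the replicate
#' AUCs is returned, clipped to contain the point estimate.
#'
#' @inheritParams auc
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 2000, seed = 1,
                         conf = 0.95) {
  l <- check_labels(labels)
  if (sum(l == 1) < 2 || sum(l == 0) < 2) {
    stop_readiff("need at least 2 cases per class", "readiff_input_error")
  }
  if (n_boot < 100) {
    warning("n_boot < 100 gives an unreliable percentile interval")
  }
  est <- auc(scores, l)
  a <- (1 - conf) / 2
  qs <- with_seed(seed, {
    stats::quantile(stratified_boot_aucs(scores, l, n_boot),
                    c(a, 1 - a), names = FALSE, type = 7)
  })
  c(low = min(qs[1], est), high = max(qs[2], est))
}

#' Full ROC summary for one score set
#'
#' @inheritParams bootstrap_ci
#' @param threshold operating threshold for the point metrics.
#' @return A `roc_result` list: `auc`, `sensitivity`, `specificity`,
#'   `accuracy`, `ci`, `n_pos`, `n_neg`.
#' @export
roc_result <- function(scores, labels, threshold = 0.5, n_boot = 2000,
                       seed = 1) {
  l <- check_labels(labels)
  m <- operating_metrics(scores, l, threshold)
  structure(list(auc = auc(scores, l),
                 sensitivity = m[["sensitivity"]],
                 specificity = m[["specificity"]],
                 accuracy = m[["accuracy"]],
                 ci = bootstrap_ci(scores, l, n_boot = n_boot, seed = seed),
                 n_pos = sum(l == 1), n_neg = sum(l == 0)),
            class = "roc_result")
}

#' Unpaired bootstrap comparison of two AUCs
#'
#' For two independent score/label sets, both are bootstrap-resampled with
#' class stratification; the observed AUC difference is standardized by the
#' bootstrap SD of the replicate differences and referred to the normal
#' distribution, two-tailed.
#'
#' @param scores_a,labels_a,scores_b,labels_b the two independent sets.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return A `comparison_result` list: `method`, `statistic` (z), `p_value`,
#'   `estimate` (AUC difference a - b), `n_boot`.
#' @export
compare_unpaired <- function(scores_a, labels_a, scores_b, labels_b,
                             n_boot = 2000, seed = 1) {
  d_obs <- auc(scores_a, labels_a) - auc(scores_b, labels_b)
  d_star <- with_seed(seed, {
    stratified_boot_aucs(scores_a, labels_a, n_boot) -
      stratified_boot_aucs(scores_b, labels_b, n_boot)
  })
  s <- stats::sd(d_star)
  z <- if (s > 0) d_obs / s else 0
  structure(list(method = "bootstrap_unpaired", statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z)), estimate = d_obs,
                 two_tailed = TRUE, alpha = 0.05, n_boot = n_boot),
            class = "comparison_result")
}

# DeLong structural components: for each positive the placement against all
# negatives, and vice versa.
delong_components <- function(scores, l) {
  sp <- scores[l == 1]; sn <- scores[l == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same cases with the
#' same labels, using the structural-component estimate of the covariance of
#' the two U-statistics; two-tailed normal reference.
#'
#' @param scores_1,scores_2 paired score vectors.
#' @param labels shared binary labels.
#' @return A `comparison_result` list: `method`, `statistic` (z), `p_value`,
#'   `estimate` (AUC1 - AUC2), `auc` (both AUCs), `var_diff`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  l <- check_labels(labels)
  if (length(scores_1) != length(l) || length(scores_2) != length(l)) {
    stop_readiff("scores and labels must be paired (equal lengths)",
                 "readiff_input_error")
  }
  c1 <- delong_components(scores_1, l)
  c2 <- delong_components(scores_2, l)
  m <- length(c1$v10); n <- length(c1$v01)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- c1$auc - c2$auc
  z <- if (var_diff > 0) d / sqrt(var_diff) else 0
  p <- if (var_diff > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(d == 0)
  structure(list(method = "delong", statistic = z, p_value = p,
                 estimate = d, auc = c(c1$auc, c2$auc), var_diff = var_diff,
                 two_tailed = TRUE, alpha = 0.05),
            class = "comparison_result")
}

# Variance of a single AUC from DeLong components (used in tests and
# reporting).
delong_var <- function(scores, labels) {
  l <- check_labels(labels)
  cc <- delong_components(scores, l)
  stats::var(cc$v10) / length(cc$v10) + stats::var(cc$v01) / length(cc$v01)
}
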