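# First-order (histogram) statistics. Histogram-based quantities (mode,
# entropy, uniformity, peak frequency) use a 32-bin equal-width histogram
# over the valid-pixel range; percentiles use R's default (type 7) rule.

hist_feature_names <- function() {
  c("hist_min", "hist_max", "hist_range", "hist_mean", "hist_median",
    "hist_mode", "hist_sd", "hist_variance", "hist_mad", "hist_rms",
    "hist_cv", "hist_skewness", "hist_kurtosis", "hist_energy",
    "hist_entropy", "hist_uniformity",
    "hist_p01", "hist_p05", "hist_p10", "hist_p25", "hist_p75", "hist_p90",
    "hist_p95", "hist_p99",
    "hist_iqr", "hist_range_p10_p90", "hist_trimmed_mean", "hist_peak_freq")
}

#' 28 first-order histogram statistics
#'
#' Location, spread, shape and histogram-derived measures of the valid pixel
#' intensities. The coefficient of variation is computed on the min-shifted
#' intensities (SD divided by the mean of `x - min(x)`) so it stays finite on
#' zero-mean (z-scored) patches; skewness is `m3/m2^1.5` and kurtosis the
#' (non-excess) `m4/m2^2`, both 0 on constant input; energy is the mean
#' square; entropy is in bits.
#'
#' @param roi a `roi_image`.
#' @param n_bins bins for the histogram-derived statistics.
#' @return Named numeric vector of length 28.
#' @export
histogram_features <- function(roi, n_bins = 32) {
  stopifnot(inherits(roi, "roi_image"))
  x <- roi_values(roi)
  if (!length(x)) stop_readiff("empty ROI", "readiff_input_error")

  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  s <- stats::sd(x)
  if (!is.finite(s)) s <- 0

  rng <- range(x)
  if (diff(rng) > 0) {
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  } else {
    cnt <- length(x)
    mids <- rng[1]
  }
  p <- cnt / sum(cnt)
  pk <- which.max(p)

  q <- stats::quantile(x, c(.01, .05, .10, .25, .50, .75, .90, .95, .99),
                       names = FALSE, type = 7)
  shift_mean <- mean(x - rng[1])

  out <- c(
    rng[1], rng[2], diff(rng), m, q[5],
    mids[pk],
    s, stats::var(if (length(x) > 1) x else c(x, x)),
    stats::mad(x, constant = 1),
    sqrt(mean(x^2)),
    if (shift_mean > 0) s / shift_mean else 0,
    if (m2 > 0) m3 / m2^1.5 else 0,
    if (m2 > 0) m4 / m2^2 else 0,
    mean(x^2),
    -sum(ifelse(p > 0, p * log2(p), 0)),
    sum(p^2),
    q[1], q[2], q[3], q[4], q[6], q[7], q[8], q[9],
    q[6] - q[4], q[7] - q[3],
    mean(x, trim = 0.1),
    max(p)
  )
  stats::setNames(out, hist_feature_names())
}
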