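# Transform-domain features: Gabor bank, RFS/MR8 maximum-response filters and
# Fourier spectrum summaries.

gabor_feature_names <- function() {
  as.vector(vapply(1:2, function(f)
    paste0("gabor_f", f, "_o", c(0, 60, 120)), character(3)))
}

rfs_feature_names <- function() {
  c(paste0("rfs_bar_s", 1:3), paste0("rfs_edge_s", 1:3), "rfs_gauss", "rfs_log")
}

fourier_feature_names <- function() c("fourier_slope", "fourier_high_frac")

gabor_kernel <- function(lambda, theta_deg, sigma = 0.56 * lambda) {
  r <- ceiling(2 * sigma)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  th <- theta_deg * pi / 180
  xp <- g$dc * cos(th) + g$dr * sin(th)
  env <- exp(-(g$dc^2 + g$dr^2) / (2 * sigma^2))
  env[g$dc^2 + g$dr^2 > r^2] <- 0  # circular truncation keeps the bank isotropic
  re <- env * cos(2 * pi * xp / lambda)
  im <- env * sin(2 * pi * xp / lambda)
  re <- re - mean(re)  # kill the DC response
  n <- 2 * r + 1
  list(re = matrix(re, n, n), im = matrix(im, n, n), radius = r)
}

# Oriented anisotropic Gaussian-derivative filter of the RFS bank.
# order 1 = edge, order 2 = bar; derivative taken across the filter axis.
rfs_kernel <- function(sx, sy, theta_deg, order) {
  r <- ceiling(2.5 * max(sx, sy))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  th <- theta_deg * pi / 180
  u <- g$dc * cos(th) + g$dr * sin(th)    # along the bar
  v <- -g$dc * sin(th) + g$dr * cos(th)   # across the bar
  base <- exp(-u^2 / (2 * sx^2)) * exp(-v^2 / (2 * sy^2))
  k <- if (order == 1) (-v / sy^2) * base else ((v^2 - sy^2) / sy^4) * base
  k <- k - mean(k)
  k <- k / sum(abs(k))
  n <- 2 * r + 1
  matrix(k, n, n)
}

gauss_kernel <- function(sigma) {
  r <- ceiling(2.5 * sigma)
  d <- (-r):r
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

log_kernel <- function(sigma) {
  r <- ceiling(2.5 * sigma)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  s2 <- g$dr^2 + g$dc^2
  k <- (s2 - 2 * sigma^2) / sigma^4 * exp(-s2 / (2 * sigma^2))
  k <- k - mean(k)
  n <- 2 * r + 1
  matrix(k / sum(abs(k)), n, n)
}

rfs_scales <- function() list(c(0.6, 1.2), c(1.2, 2.4), c(1.8, 3.6))

transform_support <- function() {
  rmax <- max(
    ceiling(2 * 0.56 * 6),                                     # gabor, lambda 6
    ceiling(2.5 * max(vapply(rfs_scales(), max, 0))),          # rfs
    ceiling(2.5 * 1.5)                                         # gauss / log
  )
  2 * rmax + 1
}

#' 16 transform-based features
#'
#' Gabor: mean response magnitude of six zero-DC complex Gabor filters (two
#' wavelengths, 3 and 6 px, times three orientations 0/60/120 degrees, with
#' sigma = 0.56 lambda). RFS: the eight maximum-response (MR8) maps - 36
#' oriented edge and bar filters (3 anisotropic scales x 6 orientations x 2
#' types) collapsed by taking the per-scale maximum absolute response over
#' orientations, plus an isotropic Gaussian and a Laplacian-of-Gaussian -
#' summarized by their mean energy (mean squared response). Fourier: the
#' log-log slope of the radially averaged power spectrum and the fraction of
#' non-DC spectral power above the median radial frequency.
#'
#' Statistics are taken over pixels whose full filter support is valid where
#' possible; invalid pixels are mean-filled before filtering.
#'
#' @param roi a `roi_image`.
#' @return Named numeric vector of length 16.
#' @export
transform_features <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  sup <- transform_support()
  if (min(dim(roi$pixels)) < sup) {
    stop_readiff(sprintf("ROI smaller than the largest filter (%d px)", sup),
                 "readiff_input_error")
  }
  x <- fill_invalid(roi)

  out <- numeric(0)
  for (fi in 1:2) {
    lambda <- c(3, 6)[fi]
    for (th in c(0, 60, 120)) {
      k <- gabor_kernel(lambda, th)
      mag <- sqrt(conv2_same(x, k$re)^2 + conv2_same(x, k$im)^2)
      ok <- interior_valid(roi$valid, k$radius)
      if (!any(ok)) ok <- roi$valid
      st <- mean(mag[ok])
      names(st) <- paste0("gabor_f", fi, "_o", th)
      out <- c(out, st)
    }
  }

  bar <- numeric(3); edge <- numeric(3)
  for (si in 1:3) {
    sc <- rfs_scales()[[si]]
    rmax <- ceiling(2.5 * sc[2])
    ok <- interior_valid(roi$valid, rmax)
    if (!any(ok)) ok <- roi$valid
    bmax <- NULL; emax <- NULL
    for (th in seq(0, 150, by = 30)) {
      rb <- abs(conv2_same(x, rfs_kernel(sc[1], sc[2], th, 2)))
      re <- abs(conv2_same(x, rfs_kernel(sc[1], sc[2], th, 1)))
      bmax <- if (is.null(bmax)) rb else pmax(bmax, rb)
      emax <- if (is.null(emax)) re else pmax(emax, re)
    }
    bar[si] <- mean(bmax[ok]^2)
    edge[si] <- mean(emax[ok]^2)
  }
  rg <- conv2_same(x, gauss_kernel(1.5))
  rl <- conv2_same(x, log_kernel(1.5))
  ok <- interior_valid(roi$valid, ceiling(2.5 * 1.5))
  if (!any(ok)) ok <- roi$valid
  rfs <- c(bar, edge, mean(rg[ok]^2), mean(rl[ok]^2))
  names(rfs) <- rfs_feature_names()
  out <- c(out, rfs)

  out <- c(out, fourier_summary(x))
  out
}

fourier_summary <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  xw <- (x - mean(x)) * outer(wr, wc)
  P <- Mod(stats::fft(xw))^2
  fr <- (seq_len(nr) - 1) / nr; fr[fr >= 0.5] <- fr[fr >= 0.5] - 1
  fc <- (seq_len(nc) - 1) / nc; fc[fc >= 0.5] <- fc[fc >= 0.5] - 1
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  keep <- rad > 0
  p <- P[keep]; r <- rad[keep]

  # radial power profile on log-spaced annuli
  br <- exp(seq(log(max(min(r), 1 / max(nr, nc))), log(0.5), length.out = 9))
  bin <- findInterval(r, br, all.inside = TRUE)
  pw <- tapply(p, bin, mean)
  rm <- tapply(r, bin, mean)
  ok <- is.finite(pw) & pw > 0
  slope <- if (sum(ok) >= 2) {
    stats::coef(stats::lm(log(pw[ok]) ~ log(rm[ok])))[[2]]
  } else 0

  med <- stats::median(r)
  high_frac <- if (sum(p) > 0) sum(p[r > med]) / sum(p) else 0
  stats::setNames(c(slope, high_frac), fourier_feature_names())
}
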