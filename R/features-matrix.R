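# Run-length, gradient-sharpness, difference-statistics, neighbourhood
# grey-tone difference and statistical-feature-matrix families. Grey levels
# enter the formulas 1-based (level + 1) so low/high grey-level weights are
# well defined.

glrlm_feature_names <- function() {
  paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre"))
}

# Runs of equal levels along the four directions; invalid pixels terminate
# runs. Returns a data frame of (level, length) per run.
extract_runs <- function(levels, valid, direction) {
  lv <- levels
  lv[!valid] <- -1L
  nr <- nrow(lv); nc <- ncol(lv)
  lines <- switch(direction,
    d0 = split(lv, row(lv)),
    d90 = split(lv, col(lv)),
    d45 = split(lv, row(lv) + col(lv)),       # anti-diagonals
    d135 = split(lv, row(lv) - col(lv))       # main diagonals
  )
  # split() on row()/col() returns elements in matrix order within groups,
  # which is the traversal order along each line
  vals <- integer(0); lens <- integer(0)
  for (ln in lines) {
    r <- rle(ln)
    keep <- r$values >= 0
    vals <- c(vals, r$values[keep])
    lens <- c(lens, r$lengths[keep])
  }
  list(level = vals, length = lens)
}

#' 7 grey-level run-length features
#'
#' Short/long run emphasis, grey-level and run-length non-uniformity, run
#' percentage and low/high grey-level run emphasis, each computed per
#' direction (0, 45, 90, 135 degrees) and averaged over the four directions.
#'
#' @param q a `quantized_roi`.
#' @return Named numeric vector of length 7.
#' @export
glrlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  np <- sum(q$valid)
  if (np == 0) stop_readiff("all pixels invalid", "readiff_input_error")
  acc <- matrix(0, 4, 7)
  dirs <- c("d0", "d45", "d90", "d135")
  for (di in seq_along(dirs)) {
    runs <- extract_runs(q$levels, q$valid, dirs[di])
    nr_runs <- length(runs$length)
    if (nr_runs == 0) stop_readiff("no runs", "readiff_input_error")
    l <- runs$length
    g <- runs$level + 1L
    acc[di, ] <- c(
      sum(1 / l^2) / nr_runs,
      sum(l^2) / nr_runs,
      sum(tapply(rep(1, nr_runs), g, sum)^2) / nr_runs,
      sum(tapply(rep(1, nr_runs), l, sum)^2) / nr_runs,
      nr_runs / np,
      sum(1 / g^2) / nr_runs,
      sum(g^2) / nr_runs
    )
  }
  stats::setNames(colMeans(acc), glrlm_feature_names())
}

glsm_feature_names <- function() {
  paste0("glsm_", c("mean", "sd", "skewness", "kurtosis", "energy", "entropy"))
}

#' 6 grey-level sharpness features
#'
#' First-order statistics (mean, SD, skewness, kurtosis, mean-square energy
#' and 32-bin histogram entropy) of the Sobel gradient-magnitude map,
#' evaluated at pixels whose full 3x3 neighbourhood is valid and interior.
#'
#' @param roi a `roi_image`.
#' @return Named numeric vector of length 6.
#' @export
glsm_features <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  x <- fill_invalid(roi)
  g <- sobel_magnitude(x)
  ok <- interior_valid(roi$valid, 1)
  v <- if (any(ok)) g[ok] else g[roi$valid]
  m <- mean(v); m2 <- mean((v - m)^2)
  ent <- {
    rng <- range(v)
    if (diff(rng) > 0) {
      br <- seq(rng[1], rng[2], length.out = 33)
      p <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = 32)
      p <- p / sum(p)
      -sum(plog2(p))
    } else 0
  }
  stats::setNames(c(m, stats::sd(v),
                    if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
                    if (m2 > 0) mean((v - m)^4) / m2^2 else 0,
                    mean(v^2), ent),
                  glsm_feature_names())
}

# Fill invalid pixels with the valid mean (for convolution-based families).
fill_invalid <- function(roi) {
  x <- roi$pixels
  if (!all(roi$valid)) x[!roi$valid] <- mean(roi$pixels[roi$valid])
  x
}

# Pixels whose (2r+1)^2 neighbourhood is entirely valid and inside the patch.
interior_valid <- function(valid, r) {
  ok <- box_sum(valid * 1, r) == (2 * r + 1)^2
  if (r > 0) {
    nr <- nrow(valid); nc <- ncol(valid)
    ok[c(seq_len(min(r, nr)), nr - seq_len(min(r, nr)) + 1), ] <- FALSE
    ok[, c(seq_len(min(r, nc)), nc - seq_len(min(r, nc)) + 1)] <- FALSE
  }
  ok & valid
}

glds_stat_names <- function() c("mean", "contrast", "asm", "entropy", "idm")

glds_feature_names <- function() {
  as.vector(vapply(c(1, 2, 4), function(d)
    paste0("glds_", glds_stat_names(), "_d", d), character(5)))
}

#' 15 grey-level difference statistics
#'
#' Histogram of absolute grey-level differences at displacements 1, 2 and 4
#' pixels, pooled over the four directions (0, 45, 90, 135 degrees); five
#' statistics per displacement: mean, contrast (second moment), angular
#' second moment, entropy and inverse difference moment.
#'
#' @param q a `quantized_roi`.
#' @return Named numeric vector of length 15.
#' @export
glds_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  out <- numeric(0)
  for (d in c(1L, 2L, 4L)) {
    offs <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
    cnt <- numeric(q$Ng)  # histogram of |difference| in 0..Ng-1
    for (off in offs) {
      pr <- offset_pairs(q$levels, q$valid, off)
      if (is.null(pr)) next
      k <- abs(pr[, 1] - pr[, 2])
      cnt <- cnt + tabulate(k + 1L, nbins = q$Ng)
    }
    if (sum(cnt) == 0) {
      stop_readiff(sprintf("no valid pixel pairs at displacement %d", d),
                   "readiff_input_error")
    }
    p <- cnt / sum(cnt)
    k <- 0:(q$Ng - 1)
    st <- c(sum(k * p), sum(k^2 * p), sum(p^2), -sum(plog2(p)),
            sum(p / (1 + k^2)))
    names(st) <- paste0("glds_", glds_stat_names(), "_d", d)
    out <- c(out, st)
  }
  out
}

ngtdm_stat_names <- function() {
  c("coarseness", "contrast", "busyness", "complexity", "strength")
}

ngtdm_feature_names <- function() {
  as.vector(vapply(c(3, 5, 7), function(n)
    paste0("ngtdm_", ngtdm_stat_names(), "_n", n), character(5)))
}

#' 15 neighbourhood grey-tone difference features
#'
#' Amadasun's coarseness, contrast, busyness, complexity and strength at
#' square neighbourhood sizes 3, 5 and 7. The neighbourhood mean excludes the
#' centre pixel and out-of-mask neighbours; centre pixels with no valid
#' neighbour are skipped. Grey levels enter 1-based.
#'
#' @param q a `quantized_roi`.
#' @return Named numeric vector of length 15.
#' @export
ngtdm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  out <- numeric(0)
  eps <- 1e-12
  for (rad in 1:3) {
    lv <- (q$levels + 1) * q$valid
    nbr_sum <- box_sum(lv, rad) - lv
    nbr_cnt <- box_sum(q$valid * 1, rad) - q$valid
    use <- q$valid & nbr_cnt >= 1
    if (!any(use)) stop_readiff("no usable neighbourhoods", "readiff_input_error")
    abar <- nbr_sum[use] / nbr_cnt[use]
    g <- q$levels[use] + 1L
    n_tot <- sum(use)
    s_i <- tapply(abs(g - abar), g, sum)
    lev <- as.integer(names(s_i))
    n_i <- tapply(rep(1, n_tot), g, sum)
    p_i <- n_i / n_tot
    ngl <- length(lev)

    psum <- sum(p_i * s_i)
    coarseness <- 1 / (eps + psum)
    if (ngl >= 2) {
      dmat <- outer(lev, lev, "-")^2
      pp <- outer(p_i, p_i)
      contrast <- (sum(pp * dmat) / (ngl * (ngl - 1))) * (sum(s_i) / n_tot)
      ipi <- lev * p_i
      den_b <- sum(abs(outer(ipi, ipi, "-")))
      busyness <- if (den_b > eps) psum / den_b else 0
      ps_i <- p_i * s_i
      num_c <- abs(outer(lev, lev, "-")) *
        (outer(ps_i, ps_i, "+")) / (n_tot * outer(p_i, p_i, "+"))
      complexity <- sum(num_c)
      strength <- sum(outer(p_i, p_i, "+") * dmat) / (eps + sum(s_i))
    } else {
      contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
    }
    st <- c(coarseness, contrast, busyness, complexity, strength)
    names(st) <- paste0("ngtdm_", ngtdm_stat_names(), "_n", 2 * rad + 1)
    out <- c(out, st)
  }
  out
}

sfm_stat_names <- function() c("coarseness", "contrast", "periodicity", "roughness")

sfm_feature_names <- function() {
  as.vector(vapply(c(4, 8), function(L)
    paste0("sfm_", sfm_stat_names(), "_L", L), character(4)))
}

# Mean absolute difference (dissimilarity) and mean squared difference
# (contrast) of valid pixel pairs at one displacement; NULL if no pairs.
sfm_delta <- function(q, off) {
  pr <- offset_pairs(q$levels, q$valid, off)
  if (is.null(pr)) return(NULL)
  d <- pr[, 1] - pr[, 2]
  c(dss = mean(abs(d)), con = mean(d^2))
}

#' 8 statistical feature matrix measures
#'
#' Inter-sample dissimilarity/contrast statistics over the displacement
#' half-plane lattice up to a maximum spacing L of 4 and 8 pixels:
#' coarseness (inverse mean dissimilarity), contrast (root mean squared
#' unit-displacement difference), periodicity (relative depth of the
#' dissimilarity minimum) and roughness (average fractal dimension estimated
#' from the log-log growth of dissimilarity along the axes).
#'
#' @param q a `quantized_roi`.
#' @return Named numeric vector of length 8.
#' @export
sfm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  out <- numeric(0)
  eps <- 1e-12
  for (L in c(4L, 8L)) {
    offs <- list()
    for (j in 1:L) offs[[length(offs) + 1]] <- c(0L, j)
    for (i in 1:L) for (j in (-L):L) offs[[length(offs) + 1]] <- c(-i, j)
    dd <- lapply(offs, function(o) sfm_delta(q, o))
    keep <- !vapply(dd, is.null, TRUE)
    dd <- dd[keep]
    if (!length(dd)) stop_readiff("patch too small for SFM", "readiff_input_error")
    dss <- vapply(dd, `[[`, 0, "dss")
    con <- vapply(dd, `[[`, 0, "con")
    offs <- offs[keep]
    cheb <- vapply(offs, function(o) max(abs(o)), 0L)

    coarseness <- length(dss) / (eps + sum(dss))
    contrast <- sqrt(mean(con[cheb == 1]))
    mdss <- mean(dss)
    periodicity <- if (mdss > eps) (mdss - min(dss)) / mdss else 0
    roughness <- mean(c(sfm_fd(q, L, axis = "h"), sfm_fd(q, L, axis = "v")))

    st <- c(coarseness, contrast, periodicity, roughness)
    names(st) <- paste0("sfm_", sfm_stat_names(), "_L", L)
    out <- c(out, st)
  }
  out
}

# Fractal dimension along one axis: 3 - H where H is the log-log slope of
# mean absolute difference versus displacement 1..L.
sfm_fd <- function(q, L, axis = c("h", "v")) {
  axis <- match.arg(axis)
  ds <- seq_len(L)
  dss <- vapply(ds, function(d) {
    off <- if (axis == "h") c(0L, d) else c(-d, 0L)
    v <- sfm_delta(q, off)
    if (is.null(v)) NA_real_ else v[["dss"]]
  }, 0)
  ok <- is.finite(dss) & dss > 0
  if (sum(ok) < 2) return(2)
  h <- stats::coef(stats::lm(log(dss[ok]) ~ log(ds[ok])))[2]
  3 - h
}
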