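# Laws texture-energy measures and fractal (box-counting) features.

laws_pairs <- function() {
  c("L5E5", "L5S5", "L5R5", "E5E5", "E5S5", "E5R5", "S5S5", "S5R5", "R5R5")
}

laws_vectors <- function() {
  list(L5 = c(1, 4, 6, 4, 1),
       E5 = c(-1, -2, 0, 2, 1),
       S5 = c(-1, 0, 2, 0, -1),
       R5 = c(1, -4, 6, -4, 1))
}

laws_feature_names <- function() {
  as.vector(vapply(laws_pairs(), function(p)
    paste0("laws_", p, c("_mean", "_sd")), character(2)))
}

#' 18 Laws texture-energy features
#'
#' The nine direction-averaged 5x5 mask pairs built from the Level, Edge,
#' Spot and Ripple vectors (L5E5 ... R5R5). For an asymmetric pair the
#' absolute responses of the two transposed masks are averaged. Each map
#' yields the mean and SD of its absolute response over pixels with a fully
#' valid 5x5 support; invalid pixels are mean-filled before convolution.
#'
#' @param roi a `roi_image`.
#' @return Named numeric vector of length 18.
#' @export
laws_features <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  if (min(dim(roi$pixels)) < 5) {
    stop_readiff("ROI smaller than the 5x5 Laws masks", "readiff_input_error")
  }
  x <- fill_invalid(roi)
  vecs <- laws_vectors()
  ok <- interior_valid(roi$valid, 2)
  if (!any(ok)) ok <- roi$valid
  out <- numeric(0)
  for (pair in laws_pairs()) {
    a <- vecs[[substr(pair, 1, 2)]]
    b <- vecs[[substr(pair, 3, 4)]]
    m1 <- abs(conv2_same(x, outer(a, b)))
    e <- if (identical(a, b)) m1 else (m1 + abs(conv2_same(x, outer(b, a)))) / 2
    v <- e[ok]
    st <- c(mean(v), stats::sd(v))
    names(st) <- paste0("laws_", pair, c("_mean", "_sd"))
    out <- c(out, st)
  }
  out
}

fractal_feature_names <- function() c("fractal_dimension", "fractal_lacunarity")

#' 2 fractal texture features
#'
#' Support-restricted differential box counting: intensities are shifted to a
#' zero minimum and scaled to 256 grey levels; at each box size the grid
#' blocks that contain signal above the global minimum contribute
#' `floor(max/h) - floor(min/h) + 1` boxes (h the height quantum for that
#' scale). Blocks flat at the minimum are not counted, so a solid uniform
#' patch has dimension 2 while sparse dots on a dark background fall below 2.
#' The dimension is the negated slope of log N versus log box size.
#' Lacunarity is the normalized second moment `E[m^2]/E[m]^2` of the block
#' masses at box size 4.
#'
#' @param roi a `roi_image`.
#' @return Named numeric vector of length 2.
#' @export
fractal_features <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi_values(roi)
  if (!length(v)) stop_readiff("empty ROI", "readiff_input_error")
  x <- roi$pixels - min(v)
  x[!roi$valid] <- 0
  mx <- max(x)
  G <- 256
  qx <- if (mx > 0) x / mx * (G - 1) else x
  flat <- mx <= 0

  M <- min(dim(qx))
  sizes <- c(2L, 3L, 4L, 6L, 8L, 12L, 16L)
  sizes <- sizes[sizes <= M / 2]
  if (length(sizes) < 2) sizes <- c(2L, max(3L, M %/% 2))

  ns <- vapply(sizes, function(s) {
    bc <- block_count(qx, roi$valid, s, G, M, flat)
    max(bc, 1)
  }, 0)
  fit <- stats::lm(log(ns) ~ log(sizes))
  fd <- -stats::coef(fit)[[2]]

  m <- block_masses(qx, roi$valid, 4L)
  lac <- if (length(m) && mean(m) > 0) mean(m^2) / mean(m)^2 else 1

  stats::setNames(c(fd, lac), fractal_feature_names())
}

block_ids <- function(nr, nc, s) {
  nr2 <- (nr %/% s) * s; nc2 <- (nc %/% s) * s
  if (nr2 == 0 || nc2 == 0) return(NULL)
  rid <- (seq_len(nr2) - 1L) %/% s
  cid <- (seq_len(nc2) - 1L) %/% s
  list(rows = nr2, cols = nc2,
       id = outer(rid, cid, function(a, b) a + (nr2 %/% s) * b))
}

block_count <- function(qx, valid, s, G, M, flat) {
  b <- block_ids(nrow(qx), ncol(qx), s)
  if (is.null(b)) return(0)
  xv <- qx[seq_len(b$rows), seq_len(b$cols), drop = FALSE]
  vv <- valid[seq_len(b$rows), seq_len(b$cols), drop = FALSE]
  id <- b$id
  h <- max(s * G / M, 1)
  mx <- tapply(ifelse(vv, xv, -Inf), id, max)
  mn <- tapply(ifelse(vv, xv, Inf), id, min)
  ok <- is.finite(mx) & is.finite(mn) & (if (flat) TRUE else mx > 0)
  if (!any(ok)) return(0)
  sum(floor(mx[ok] / h) - floor(mn[ok] / h) + 1)
}

block_masses <- function(qx, valid, s) {
  b <- block_ids(nrow(qx), ncol(qx), s)
  if (is.null(b)) return(numeric(0))
  xv <- qx[seq_len(b$rows), seq_len(b$cols), drop = FALSE] *
    valid[seq_len(b$rows), seq_len(b$cols), drop = FALSE]
  as.numeric(tapply(xv, b$id, sum))
}
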