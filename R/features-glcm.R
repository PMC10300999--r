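# Grey-level co-occurrence features: 22 statistics x 4 offsets (distance 1 at
# 0/45/90/135 degrees) = 88. Co-occurrence matrices are symmetric and
# normalized; pixel pairs with an invalid member are skipped.

glcm_offsets <- function() {
  list(d0 = c(0L, 1L), d45 = c(-1L, 1L), d90 = c(-1L, 0L), d135 = c(-1L, -1L))
}

glcm_stat_names <- function() {
  c("asm", "contrast", "correlation", "sum_of_squares", "idm",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "diff_variance", "diff_entropy", "imc1", "imc2",
    "autocorrelation", "cluster_shade", "cluster_prominence",
    "dissimilarity", "homogeneity", "idn", "idmn", "max_prob",
    "joint_variance")
}

glcm_feature_names <- function() {
  as.vector(t(outer(names(glcm_offsets()),
                    glcm_stat_names(),
                    function(o, s) paste0("glcm_", s, "_", o))))
}

# Shifted index pairs of valid pixels for an offset (dr, dc); returns a
# 2-column matrix of 1-based levels (level + 1).
offset_pairs <- function(levels, valid, off) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- off[1]; dc <- off[2]
  if (max(1, 1 - dr) > min(nr, nr - dr) ||
      max(1, 1 - dc) > min(nc, nc - dc)) return(NULL)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a_ok <- valid[r1, c1, drop = FALSE] & valid[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(a_ok)) return(NULL)
  cbind(levels[r1, c1, drop = FALSE][a_ok],
        levels[r1 + dr, c1 + dc, drop = FALSE][a_ok]) + 1L
}

glcm_matrix <- function(q, off) {
  pr <- offset_pairs(q$levels, q$valid, off)
  if (is.null(pr)) return(NULL)
  Ng <- q$Ng
  cnt <- matrix(tabulate(pr[, 1] + Ng * (pr[, 2] - 1L), nbins = Ng * Ng),
                Ng, Ng)
  cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

plog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

glcm_stats <- function(p) {
  Ng <- nrow(p)
  i <- seq_len(Ng)
  ii <- matrix(i, Ng, Ng)
  jj <- t(ii)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sd_x <- sqrt(sum((i - mu_x)^2 * px)); sd_y <- sqrt(sum((i - mu_y)^2 * py))

  k_sum <- as.integer(rownames(rs <- rowsum(as.vector(p), as.vector(ii + jj))))
  p_sum <- as.vector(rs)
  k_dif <- as.integer(rownames(rd <- rowsum(as.vector(p), as.vector(abs(ii - jj)))))
  p_dif <- as.vector(rd)

  hxy <- -sum(plog2(p))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(p > 0, p * log2(pmax(pxy, 1e-300)), 0))
  hxy2 <- -sum(plog2(pxy))
  hx <- -sum(plog2(px)); hy <- -sum(plog2(py))

  sum_avg <- sum(k_sum * p_sum)
  mu_d <- sum(k_dif * p_dif)
  mu <- (mu_x + mu_y) / 2

  c(
    asm = sum(p^2),
    contrast = sum((ii - jj)^2 * p),
    correlation = if (sd_x * sd_y > 1e-12)
      (sum(ii * jj * p) - mu_x * mu_y) / (sd_x * sd_y) else 0,
    sum_of_squares = sum((ii - mu_x)^2 * p),
    idm = sum(p / (1 + (ii - jj)^2)),
    sum_average = sum_avg,
    sum_variance = sum((k_sum - sum_avg)^2 * p_sum),
    sum_entropy = -sum(plog2(p_sum)),
    entropy = hxy,
    diff_variance = sum((k_dif - mu_d)^2 * p_dif),
    diff_entropy = -sum(plog2(p_dif)),
    imc1 = if (max(hx, hy) > 1e-12) (hxy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    autocorrelation = sum(ii * jj * p),
    cluster_shade = sum((ii + jj - mu_x - mu_y)^3 * p),
    cluster_prominence = sum((ii + jj - mu_x - mu_y)^4 * p),
    dissimilarity = sum(abs(ii - jj) * p),
    homogeneity = sum(p / (1 + abs(ii - jj))),
    idn = sum(p / (1 + abs(ii - jj) / Ng)),
    idmn = sum(p / (1 + (ii - jj)^2 / Ng^2)),
    max_prob = max(p),
    joint_variance = sum(((ii - mu)^2 + (jj - mu)^2) / 2 * p)
  )
}

#' 88 grey-level co-occurrence features
#'
#' Symmetric, normalized co-occurrence at distance 1 for the four standard
#' 2-D offsets (0, 45, 90 and 135 degrees), kept separate per offset: the 13
#' Haralick statistics plus autocorrelation, cluster shade and prominence,
#' dissimilarity, homogeneity (inverse difference), inverse difference
#' normalized, inverse difference moment normalized, maximum probability and
#' the joint grey-level variance. Grey levels enter the formulas 1-based.
#'
#' @param q a `quantized_roi`.
#' @return Named numeric vector of length 88.
#' @export
glcm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!any(q$valid)) stop_readiff("all pixels invalid", "readiff_input_error")
  out <- numeric(0)
  for (oname in names(glcm_offsets())) {
    p <- glcm_matrix(q, glcm_offsets()[[oname]])
    if (is.null(p)) {
      stop_readiff(sprintf("no valid pixel pairs for offset %s", oname),
                   "readiff_input_error")
    }
    st <- glcm_stats(p)
    names(st) <- paste0("glcm_", names(st), "_", oname)
    out <- c(out, st)
  }
  out[glcm_feature_names()]
}
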