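# Naive double-loop oracle implementations of the matrix-based texture
# families, written independently of the package's vectorized code. All use
# plain per-pixel loops and the documented formulas.

oracle_quantize <- function(roi, Ng = 32) {
  v <- roi$pixels[roi$valid]
  lv <- floor((roi$pixels - min(v)) / (max(v) - min(v)) * Ng)
  lv[lv >= Ng] <- Ng - 1
  lv[!roi$valid] <- 0
  list(levels = lv, valid = roi$valid, Ng = Ng)
}

# --- GLCM ------------------------------------------------------------------

oracle_glcm_matrix <- function(q, dr, dc) {
  Ng <- q$Ng
  cnt <- matrix(0, Ng, Ng)
  nr <- nrow(q$levels); nc <- ncol(q$levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!q$valid[r, c] || !q$valid[r2, c2]) next
    a <- q$levels[r, c] + 1; b <- q$levels[r2, c2] + 1
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  cnt / sum(cnt)
}

oracle_glcm_stats <- function(p) {
  Ng <- nrow(p)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((1:Ng) * px); mu_y <- sum((1:Ng) * py)
  sd_x <- sqrt(sum(((1:Ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:Ng) - mu_y)^2 * py))
  mu <- (mu_x + mu_y) / 2

  p_sum <- numeric(2 * Ng); p_dif <- numeric(Ng)
  asm <- contrast <- cor_n <- ssq <- idm <- ent <- 0
  autoc <- shade <- prom <- dissim <- homog <- idn <- idmn <- jvar <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    v <- p[i, j]
    p_sum[i + j] <- p_sum[i + j] + v
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + v
    asm <- asm + v^2
    contrast <- contrast + (i - j)^2 * v
    cor_n <- cor_n + i * j * v
    ssq <- ssq + (i - mu_x)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    ent <- ent - v * lg2(v)
    autoc <- autoc + i * j * v
    shade <- shade + (i + j - mu_x - mu_y)^3 * v
    prom <- prom + (i + j - mu_x - mu_y)^4 * v
    dissim <- dissim + abs(i - j) * v
    homog <- homog + v / (1 + abs(i - j))
    idn <- idn + v / (1 + abs(i - j) / Ng)
    idmn <- idmn + v / (1 + (i - j)^2 / Ng^2)
    jvar <- jvar + ((i - mu)^2 + (j - mu)^2) / 2 * v
    if (v > 0) hxy1 <- hxy1 - v * lg2(px[i] * py[j])
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * lg2(px[i] * py[j])
  }
  sum_avg <- sum((2:(2 * Ng)) * p_sum[2:(2 * Ng)])
  sum_var <- sum(((2:(2 * Ng)) - sum_avg)^2 * p_sum[2:(2 * Ng)])
  sum_ent <- -sum(sapply(p_sum, function(v) v * lg2(v)))
  mu_d <- sum((0:(Ng - 1)) * p_dif)
  dif_var <- sum(((0:(Ng - 1)) - mu_d)^2 * p_dif)
  dif_ent <- -sum(sapply(p_dif, function(v) v * lg2(v)))
  hx <- -sum(sapply(px, function(v) v * lg2(v)))
  hy <- -sum(sapply(py, function(v) v * lg2(v)))
  imc1 <- if (max(hx, hy) > 1e-12) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  correlation <- if (sd_x * sd_y > 1e-12) (cor_n - mu_x * mu_y) / (sd_x * sd_y) else 0

  c(asm = asm, contrast = contrast, correlation = correlation,
    sum_of_squares = ssq, idm = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = ent,
    diff_variance = dif_var, diff_entropy = dif_ent, imc1 = imc1,
    imc2 = imc2, autocorrelation = autoc, cluster_shade = shade,
    cluster_prominence = prom, dissimilarity = dissim, homogeneity = homog,
    idn = idn, idmn = idmn, max_prob = max(p), joint_variance = jvar)
}

oracle_glcm_features <- function(q) {
  offs <- list(d0 = c(0, 1), d45 = c(-1, 1), d90 = c(-1, 0), d135 = c(-1, -1))
  out <- numeric(0)
  for (o in names(offs)) {
    st <- oracle_glcm_stats(oracle_glcm_matrix(q, offs[[o]][1], offs[[o]][2]))
    names(st) <- paste0("glcm_", names(st), "_", o)
    out <- c(out, st)
  }
  out
}

# --- GLRLM -----------------------------------------------------------------

oracle_runs_along <- function(q, step) {
  nr <- nrow(q$levels); nc <- ncol(q$levels)
  # line starting points: cells with no predecessor along `step`
  runs_level <- integer(0); runs_len <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    pr <- r0 - step[1]; pc <- c0 - step[2]
    if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next  # not a line start
    r <- r0; c <- c0
    cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      lv <- if (q$valid[r, c]) q$levels[r, c] else NA
      if (!is.na(lv) && !is.na(cur) && lv == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) { runs_level <- c(runs_level, cur); runs_len <- c(runs_len, len) }
        cur <- lv; len <- if (is.na(lv)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur)) { runs_level <- c(runs_level, cur); runs_len <- c(runs_len, len) }
  }
  list(level = runs_level, length = runs_len)
}

oracle_glrlm_features <- function(q) {
  steps <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  np <- sum(q$valid)
  acc <- NULL
  for (s in steps) {
    runs <- oracle_runs_along(q, s)
    nr_runs <- length(runs$length)
    l <- runs$length; g <- runs$level + 1
    f <- c(sre = sum(1 / l^2) / nr_runs,
           lre = sum(l^2) / nr_runs,
           gln = sum(table(g)^2) / nr_runs,
           rln = sum(table(l)^2) / nr_runs,
           rp = nr_runs / np,
           lgre = sum(1 / g^2) / nr_runs,
           hgre = sum(g^2) / nr_runs)
    acc <- rbind(acc, f)
  }
  stats::setNames(colMeans(acc), paste0("glrlm_", colnames(acc)))
}

# --- GLDS ------------------------------------------------------------------

oracle_glds_features <- function(q) {
  nr <- nrow(q$levels); nc <- ncol(q$levels)
  out <- numeric(0)
  for (d in c(1, 2, 4)) {
    cnt <- numeric(q$Ng)
    for (off in list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))) {
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!q$valid[r, c] || !q$valid[r2, c2]) next
        k <- abs(q$levels[r, c] - q$levels[r2, c2])
        cnt[k + 1] <- cnt[k + 1] + 1
      }
    }
    p <- cnt / sum(cnt)
    k <- 0:(q$Ng - 1)
    st <- c(sum(k * p), sum(k^2 * p), sum(p^2),
            -sum(sapply(p, function(v) if (v > 0) v * log2(v) else 0)),
            sum(p / (1 + k^2)))
    names(st) <- paste0("glds_", c("mean", "contrast", "asm", "entropy", "idm"),
                        "_d", d)
    out <- c(out, st)
  }
  out
}

# --- NGTDM -----------------------------------------------------------------

oracle_ngtdm_features <- function(q) {
  nr <- nrow(q$levels); nc <- ncol(q$levels)
  out <- numeric(0)
  for (rad in 1:3) {
    s_of <- list(); n_of <- list()
    n_tot <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!q$valid[r, c]) next
      nb <- c()
      for (dr in -rad:rad) for (dc in -rad:rad) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (q$valid[r2, c2]) nb <- c(nb, q$levels[r2, c2] + 1)
      }
      if (!length(nb)) next
      g <- as.character(q$levels[r, c] + 1)
      s_of[[g]] <- (s_of[[g]] %||% 0) + abs(q$levels[r, c] + 1 - mean(nb))
      n_of[[g]] <- (n_of[[g]] %||% 0) + 1
      n_tot <- n_tot + 1
    }
    lev <- as.integer(names(s_of))
    s_i <- unlist(s_of); p_i <- unlist(n_of) / n_tot
    ngl <- length(lev)
    eps <- 1e-12
    coarse <- 1 / (eps + sum(p_i * s_i))
    contrast <- busy <- cplx <- strength <- 0
    if (ngl >= 2) {
      den_b <- 0
      for (a in seq_len(ngl)) for (b in seq_len(ngl)) {
        contrast <- contrast + p_i[a] * p_i[b] * (lev[a] - lev[b])^2
        den_b <- den_b + abs(lev[a] * p_i[a] - lev[b] * p_i[b])
        cplx <- cplx + abs(lev[a] - lev[b]) *
          (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (n_tot * (p_i[a] + p_i[b]))
        strength <- strength + (p_i[a] + p_i[b]) * (lev[a] - lev[b])^2
      }
      contrast <- contrast / (ngl * (ngl - 1)) * sum(s_i) / n_tot
      busy <- if (den_b > eps) sum(p_i * s_i) / den_b else 0
      strength <- strength / (eps + sum(s_i))
    }
    st <- c(coarse, contrast, busy, cplx, strength)
    names(st) <- paste0("ngtdm_",
                        c("coarseness", "contrast", "busyness", "complexity",
                          "strength"), "_n", 2 * rad + 1)
    out <- c(out, st)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- SFM -------------------------------------------------------------------

oracle_sfm_pair_stats <- function(q, dr, dc) {
  nr <- nrow(q$levels); nc <- ncol(q$levels)
  dif <- c()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!q$valid[r, c] || !q$valid[r2, c2]) next
    dif <- c(dif, q$levels[r, c] - q$levels[r2, c2])
  }
  if (!length(dif)) return(NULL)
  c(dss = mean(abs(dif)), con = mean(dif^2))
}

oracle_sfm_features <- function(q) {
  eps <- 1e-12
  out <- numeric(0)
  for (L in c(4, 8)) {
    offs <- list()
    for (j in 1:L) offs[[length(offs) + 1]] <- c(0, j)
    for (i in 1:L) for (j in (-L):L) offs[[length(offs) + 1]] <- c(-i, j)
    st <- lapply(offs, function(o) oracle_sfm_pair_stats(q, o[1], o[2]))
    keep <- !sapply(st, is.null)
    st <- st[keep]; offs <- offs[keep]
    dss <- sapply(st, `[[`, "dss"); con <- sapply(st, `[[`, "con")
    cheb <- sapply(offs, function(o) max(abs(o)))
    fd_axis <- function(step) {
      ds <- 1:L
      v <- sapply(ds, function(d) {
        s <- oracle_sfm_pair_stats(q, step[1] * d, step[2] * d)
        if (is.null(s)) NA else s[["dss"]]
      })
      ok <- is.finite(v) & v > 0
      if (sum(ok) < 2) return(2)
      3 - stats::coef(stats::lm(log(v[ok]) ~ log(ds[ok])))[[2]]
    }
    f <- c(length(dss) / (eps + sum(dss)),
           sqrt(mean(con[cheb == 1])),
           if (mean(dss) > eps) (mean(dss) - min(dss)) / mean(dss) else 0,
           mean(c(fd_axis(c(0, 1)), fd_axis(c(-1, 0)))))
    names(f) <- paste0("sfm_", c("coarseness", "contrast", "periodicity",
                                 "roughness"), "_L", L)
    out <- c(out, f)
  }
  out
}

# --- largest inscribed square ---------------------------------------------

oracle_largest_square <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  best <- list(side = 0, top = NA, left = NA)
  for (s in seq_len(min(nr, nc))) {
    found <- FALSE
    for (i in seq_len(nr - s + 1)) {
      for (j in seq_len(nc - s + 1)) {
        if (all(mask[i:(i + s - 1), j:(j + s - 1)])) {
          if (s > best$side) best <- list(side = s, top = i, left = j)
          found <- TRUE
          break  # first (smallest row, then col) hit at this size
        }
      }
      if (found) break
    }
    if (!found && s > best$side) break
  }
  if (best$side == 0) NULL else best
}

# --- AUC -------------------------------------------------------------------

oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
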