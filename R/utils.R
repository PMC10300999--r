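#' @keywords internal
"_PACKAGE"

# Deterministic seed for a named substream of a master seed. All randomness in
# the package flows from one integer seed through named substreams, so stages
# (cohort generation, reader panel, fold plan, forests, bootstrap) are
# independently reproducible. FNV-style mixing kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  s <- (abs(seed) %% m)
  for (ch in utf8ToInt(as.character(name))) {
    s <- (s * 131 + ch) %% m
  }
  as.integer(if (s == 0) 1 else s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

stop_readiff <- function(msg, class) {
  stop(structure(
    class = c(class, "readiff_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Standard mammographic view tags
#'
#' The four standard screening projections: left/right craniocaudal and
#' mediolateral-oblique.
#' @return Character vector `c("LCC", "RCC", "LMLO", "RMLO")`.
#' @export
view_tags <- function() c("LCC", "RCC", "LMLO", "RMLO")

is_mlo <- function(view_tag) grepl("MLO$", view_tag)
is_right <- function(view_tag) startsWith(view_tag, "R")

#' Orient a view so the chest wall is on the left
#'
#' All segmentation and ROI code assumes the chest wall lies along the left
#' image border. Right-sided views are mirrored horizontally.
#'
#' @param view numeric matrix (rows = image rows).
#' @param view_tag one of `view_tags()`.
#' @return The (possibly mirrored) matrix.
#' @export
orient_chest_left <- function(view, view_tag) {
  if (is_right(view_tag)) view[, ncol(view):1, drop = FALSE] else view
}

# Simple polynomial content hash over the serialized object, used for
# provenance stamps in manifests.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  m <- 2147483647
  h <- 0
  for (b in as.integer(raw)) h <- (h * 131 + b) %% m
  sprintf("%08x", as.integer(h))
}

# 2-D "same" convolution / cross-correlation with zero padding, direct
# (non-FFT) so small kernels on small patches are exact and fast.
conv2_same <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(x); nc <- ncol(x)
  pr <- kr %/% 2L; pc <- kc %/% 2L
  xp <- matrix(0, nr + 2 * pr, nc + 2 * pc)
  xp[(pr + 1):(pr + nr), (pc + 1):(pc + nc)] <- x
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * xp[(i):(i + nr - 1), (j):(j + nc - 1)]
    }
  }
  out
}

# Box-filter sums of x over a (2r+1)^2 window via summed-area tables.
box_sum <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  xp <- matrix(0, nr + 2 * r, nc + 2 * r)
  xp[(r + 1):(r + nr), (r + 1):(r + nc)] <- x
  sat <- apply(apply(xp, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  w <- 2 * r + 1
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  sat[i1 + w, j1 + w, drop = FALSE] - sat[i1, j1 + w, drop = FALSE] -
    sat[i1 + w, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
}
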