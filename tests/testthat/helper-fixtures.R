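# Shared fixtures, built in code.

# Random-texture ROI patch, optionally with invalid (out-of-mask) pixels.
rand_roi <- function(nr = 8, nc = 8, seed = 1, holes = FALSE, smooth = FALSE) {
  set.seed(seed)
  x <- matrix(runif(nr * nc), nr, nc)
  if (smooth) {
    k <- matrix(1 / 9, 3, 3)
    x <- readiff:::conv2_same(x, k)
  }
  valid <- matrix(TRUE, nr, nc)
  if (holes) {
    valid[sample(nr * nc, round(0.15 * nr * nc))] <- FALSE
    if (!any(valid)) valid[1] <- TRUE
  }
  roi_image(x, valid)
}

const_roi <- function(value = 1, nr = 16, nc = 16) {
  roi_image(matrix(value, nr, nc))
}

# Minimal case records (no images) for reader-panel simulation.
stub_cohort <- function(n, d = NULL, cancer = FALSE, seed = 1) {
  set.seed(seed)
  if (is.null(d)) d <- rnorm(n)
  cases <- lapply(seq_len(n), function(i) {
    structure(list(case_id = sprintf("case%03d", i), cancer = cancer,
                   lesion = if (cancer) {
                     list(side = "L",
                          views = list(LCC = c(50, 50), LMLO = c(60, 40)))
                   } else NULL),
              class = "case_record")
  })
  truth <- data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
                      cancer = cancer, latent_difficulty = d)
  list(cases = cases, truth = truth)
}

# One small generated case, memoized across tests in a session.
.fixture_env <- new.env()
demo_case <- function(image_size = 192, seed = 7, index = 3) {
  key <- sprintf("case_%d_%d_%d", image_size, seed, index)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(n_normal = 2, n_cancer = 1,
                            image_size = image_size, seed = seed)
    .fixture_env[[key]] <- list(config = cfg, case = generate_case(cfg, index))
  }
  .fixture_env[[key]]
}
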