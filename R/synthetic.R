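#' Configuration for a synthetic screening cohort
#'
#' Defines the study conditions for a simulated mammography reading study:
#' a set of screening cases (four views each, built as clustered lumpy
#' backgrounds inside a half-disc breast silhouette, with a bright pectoral
#' wedge on MLO views and a single Gaussian lesion on cancer cases) and a
#' panel of readers whose per-case error probability depends on the image
#' texture through a logistic link.
#'
#' Each case draws a blob parameter set (count, width, amplitudes) shared by
#' its four views: one case-level blob width is drawn uniformly on
#' `blob_sigma_range` and used for all of the case's blobs, so texture
#' coarseness varies meaningfully from case to case. The latent difficulty
#' `d_c` is that width standardized by the uniform-draw moments: wider blobs
#' give coarser texture in which findings are harder to call. A reader `r`
#' errs on case `c` with probability
#' `plogis(error_link_intercept + error_link_slope * d_c + b_r)` where
#' `b_r ~ Normal(0, reader_bias_sd)`. With `error_link_slope = 0` errors are
#' independent of texture (null condition).
#'
#' @param n_normal,n_cancer number of cancer-free and cancer cases (>= 1).
#' @param image_size side of the square views in pixels (>= 64).
#' @param blob_count_range integer interval for the per-case number of
#'   Gaussian blobs.
#' @param blob_sigma_range interval (pixels) for blob standard deviations.
#' @param blob_amplitude_range intensity interval for blob amplitudes.
#' @param lesion_contrast,lesion_sigma amplitude and width (pixels) of the
#'   inserted Gaussian lesion on cancer cases.
#' @param n_readers panel size (>= 1).
#' @param error_link_intercept logistic intercept (log-odds of error for an
#'   average case and unbiased reader).
#' @param error_link_slope strength of the texture-to-error coupling (beta).
#' @param reader_bias_sd standard deviation of the per-reader bias.
#' @param noise_sd SD of additive Gaussian detector noise inside the breast
#'   (keeps even blob-free regions from being exactly constant, as on any
#'   real detector).
#' @param loc_error_frac probability that an error on a cancer case manifests
#'   as a localization error (positive call, displaced annotation) rather
#'   than a miss.
#' @param loc_radius correct-localization radius in pixels at this image
#'   scale. Defaults to 7% of `image_size`; lesions are placed so that the
#'   whole displacement annulus `(loc_radius, 2*loc_radius]` stays on-breast.
#' @param seed master integer seed; all stages derive named substreams.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_normal = 40, n_cancer = 20, image_size = 192,
                             blob_count_range = c(30L, 60L),
                             blob_sigma_range = c(2, 8),
                             blob_amplitude_range = c(0.15, 0.45),
                             lesion_contrast = 0.5, lesion_sigma = 3,
                             n_readers = 20,
                             error_link_intercept = qlogis(0.3),
                             error_link_slope = 2,
                             reader_bias_sd = 0.5,
                             noise_sd = 0.02,
                             loc_error_frac = 0.5,
                             loc_radius = round(0.07 * image_size),
                             seed = 1L) {
  cfg <- list(
    n_normal = as.integer(n_normal), n_cancer = as.integer(n_cancer),
    image_size = as.integer(image_size),
    blob_count_range = as.integer(blob_count_range),
    blob_sigma_range = as.numeric(blob_sigma_range),
    blob_amplitude_range = as.numeric(blob_amplitude_range),
    lesion_contrast = lesion_contrast, lesion_sigma = lesion_sigma,
    n_readers = as.integer(n_readers),
    error_link_intercept = error_link_intercept,
    error_link_slope = error_link_slope,
    reader_bias_sd = reader_bias_sd,
    noise_sd = noise_sd,
    loc_error_frac = loc_error_frac,
    loc_radius = as.integer(loc_radius),
    seed = as.integer(seed)
  )
  if (cfg$n_normal < 1 || cfg$n_cancer < 1 || cfg$n_readers < 1) {
    stop_readiff("n_normal, n_cancer and n_readers must all be >= 1",
                 "readiff_config_error")
  }
  if (cfg$image_size < 64) {
    stop_readiff("image_size must be >= 64 pixels", "readiff_config_error")
  }
  for (f in c("blob_count_range", "blob_sigma_range", "blob_amplitude_range")) {
    if (length(cfg[[f]]) != 2 || diff(cfg[[f]]) < 0) {
      stop_readiff(sprintf("%s must be a non-decreasing interval", f),
                   "readiff_config_error")
    }
  }
  if (cfg$loc_radius < 2) {
    stop_readiff("loc_radius must be >= 2 pixels", "readiff_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

# Half-disc breast silhouette, chest wall on the given side.
breast_silhouette <- function(size, chest = c("left", "right")) {
  chest <- match.arg(chest)
  r0 <- size / 2
  radius <- 0.46 * size
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  edge_col <- if (chest == "left") 1 else size
  mask <- sqrt((rows - r0)^2 + (cols - edge_col)^2) <= radius
  mask
}

# Triangular pectoral wedge in the chest-wall top corner, intersected with
# the silhouette. Line runs from (row 1, col c_top) to (row r_bot, col 1) in
# chest-left orientation; `angle` below is its inclination from vertical.
pectoral_wedge <- function(size, c_top, r_bot, silhouette, right = FALSE) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  if (right) cols <- size + 1 - cols
  wedge <- (cols - 1) / c_top + (rows - 1) / r_bot < 1
  wedge & silhouette
}

#' Generate one synthetic screening case
#'
#' Builds the four standard views (LCC, RCC, LMLO, RMLO) as clustered lumpy
#' backgrounds: a sum of Gaussian blobs inside a half-disc breast silhouette
#' on a dark background, with a bright triangular pectoral wedge in the
#' chest-wall top corner of MLO views. Cases with `case_index > n_normal`
#' carry one Gaussian lesion in the CC and MLO views of one side, at recorded
#' pixel locations. Deterministic given `(config$seed, case_index)`.
#'
#' The latent difficulty `d_c` is a deterministic function of the drawn blob
#' parameters: the case-level blob width standardized by the theoretical
#' moments of its uniform draw,
#' `(sigma_case - midpoint(blob_sigma_range)) / (width(blob_sigma_range) /
#' sqrt(12))` (0 when the range is degenerate).
#'
#' @param config a [synthetic_config()].
#' @param case_index 1-based index; indices `1..n_normal` are cancer-free.
#' @return A `case_record`: list with `case_id`, `cancer`, `views` (named
#'   list of numeric matrices, row/col indexed), `silhouette` (logical
#'   matrix per laterality), `wedges` (logical masks for the MLO views),
#'   `lesion` (NULL or list with `side` and per-view `(row, col)` centres)
#'   and `meta` (blob draws and `latent_difficulty`).
#' @export
generate_case <- function(config, case_index) {
  stopifnot(inherits(config, "synthetic_config"))
  case_index <- as.integer(case_index)
  n_total <- config$n_normal + config$n_cancer
  if (case_index < 1 || case_index > n_total) {
    stop_readiff("case_index out of range", "readiff_input_error")
  }
  cancer <- case_index > config$n_normal
  size <- config$image_size
  with_seed(substream_seed(config$seed, paste0("case", case_index)), {
    nb <- if (diff(config$blob_count_range) == 0) config$blob_count_range[1] else
      sample(config$blob_count_range[1]:config$blob_count_range[2], 1)
    sr <- config$blob_sigma_range
    sigma_case <- runif(1, sr[1], sr[2])
    sigmas <- rep(sigma_case, nb)
    amps <- runif(nb, config$blob_amplitude_range[1], config$blob_amplitude_range[2])
    d_c <- if (diff(sr) > 0) (sigma_case - mean(sr)) / (diff(sr) / sqrt(12)) else 0

    sil_left <- breast_silhouette(size, "left")
    sil_right <- breast_silhouette(size, "right")
    sil_idx <- list(left = which(sil_left), right = which(sil_right))

    lesion <- NULL
    if (cancer) {
      side <- sample(c("L", "R"), 1)
      lesion <- list(side = side, views = list())
    }

    views <- list()
    wedges <- list()
    for (tag in view_tags()) {
      right <- is_right(tag)
      sil <- if (right) sil_right else sil_left
      img <- matrix(0, size, size)
      img[sil] <- 0.6  # baseline tissue intensity, well above background

      # blob centres uniform over the silhouette
      centres <- sample(sil_idx[[if (right) "right" else "left"]], nb,
                        replace = TRUE)
      cr <- (centres - 1) %% size + 1
      cc <- (centres - 1) %/% size + 1
      for (b in seq_len(nb)) {
        img <- add_gaussian(img, cr[b], cc[b], sigmas[b], amps[b])
      }

      if (is_mlo(tag)) {
        c_top <- runif(1, 0.28, 0.42) * size
        r_bot <- runif(1, 0.35, 0.60) * size
        w <- pectoral_wedge(size, c_top, r_bot, sil, right = right)
        img[w] <- img[w] + 1.2 * config$blob_amplitude_range[2]
        wedges[[tag]] <- w
        attr(wedges[[tag]], "c_top") <- c_top
        attr(wedges[[tag]], "r_bot") <- r_bot
      }

      if (cancer && startsWith(tag, lesion$side)) {
        pos <- sample_lesion_site(sil, size, right,
                                  margin = 2 * config$loc_radius + 2)
        img <- add_gaussian(img, pos[1], pos[2], config$lesion_sigma,
                            config$lesion_contrast)
        lesion$views[[tag]] <- pos
      }
      img[sil] <- pmax(0, img[sil] + rnorm(sum(sil), 0, config$noise_sd))
      img[!sil] <- 0
      views[[tag]] <- img
    }

    structure(list(
      case_id = sprintf("case%03d", case_index),
      cancer = cancer,
      views = views,
      silhouette = list(left = sil_left, right = sil_right),
      wedges = wedges,
      lesion = lesion,
      meta = list(n_blobs = nb, sigmas = sigmas, amplitudes = amps,
                  latent_difficulty = d_c)
    ), class = "case_record")
  })
}

add_gaussian <- function(img, r0, c0, sigma, amp) {
  size_r <- nrow(img); size_c <- ncol(img)
  w <- ceiling(3 * sigma)
  rs <- max(1, r0 - w):min(size_r, r0 + w)
  cs <- max(1, c0 - w):min(size_c, c0 + w)
  g <- amp * exp(-outer((rs - r0)^2, (cs - c0)^2, "+") / (2 * sigma^2))
  img[rs, cs] <- img[rs, cs] + g
  img
}

# Uniformly sample an in-silhouette pixel at least `margin` pixels away from
# the silhouette boundary (so an annulus of that radius stays on-breast).
sample_lesion_site <- function(sil, size, right, margin) {
  r0 <- size / 2
  radius <- 0.46 * size
  edge_col <- if (right) size else 1
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  d_centre <- sqrt((rows - r0)^2 + (cols - edge_col)^2)
  ok <- sil & (d_centre <= radius - margin) & (abs(cols - edge_col) >= margin)
  idx <- which(ok)
  if (!length(idx)) {
    stop_readiff("image too small for the configured localization radius",
                 "readiff_config_error")
  }
  i <- if (length(idx) == 1) idx else sample(idx, 1)
  c((i - 1) %% size + 1, (i - 1) %/% size + 1)
}

#' Generate a full synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @return Object of class `synthetic_cohort`: list with `cases` (list of
#'   `case_record`), `truth` (data frame: `case_id`, `cancer`,
#'   `latent_difficulty`, `expected_error_prob` — the error probability of an
#'   unbiased reader), `lesions` (data frame: `case_id`, `view`, `x`, `y`,
#'   with `x` = column, `y` = row) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_normal + config$n_cancer
  cases <- lapply(seq_len(n), function(i) generate_case(config, i))
  truth <- data.frame(
    case_id = vapply(cases, `[[`, "", "case_id"),
    cancer = vapply(cases, `[[`, NA, "cancer"),
    latent_difficulty = vapply(cases, function(x) x$meta$latent_difficulty, 0)
  )
  truth$expected_error_prob <- plogis(config$error_link_intercept +
                                        config$error_link_slope * truth$latent_difficulty)
  lesions <- do.call(rbind, lapply(cases, function(cs) {
    if (is.null(cs$lesion)) return(NULL)
    data.frame(case_id = cs$case_id, view = names(cs$lesion$views),
               x = vapply(cs$lesion$views, `[[`, 0, 2),
               y = vapply(cs$lesion$views, `[[`, 0, 1))
  }))
  structure(list(cases = cases, truth = truth, lesions = lesions,
                 config = config),
            class = "synthetic_cohort")
}

#' Simulate a reader panel over a cohort
#'
#' Each reader `r` gets a bias `b_r ~ Normal(0, reader_bias_sd)` and errs on
#' case `c` with probability `plogis(alpha + beta * d_c + b_r)`. On a
#' cancer-free case an error is a false-positive call (rating 3-5); a
#' non-error emits rating 1-2. On a cancer case a non-error emits a rating
#' >= 3 with an annotation inside the correct-localization radius of the true
#' lesion; an error is, with probability `loc_error_frac`, a localization
#' error (rating >= 3, annotation displaced uniformly on the annulus
#' `(loc_radius, 2*loc_radius]` around the lesion) and otherwise a miss
#' (rating <= 2, no annotation).
#'
#' @param cases list of `case_record`s.
#' @param truth truth data frame with `case_id` and `latent_difficulty`
#'   (one row per case, as produced by [generate_cohort()]).
#' @param config the [synthetic_config()] used.
#' @return Data frame of reader responses: `reader_id`, `case_id`, `rating`,
#'   `view`, `x`, `y` (`x` = column, `y` = row; NA when unannotated).
#' @export
simulate_reader_panel <- function(cases, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- vapply(cases, `[[`, "", "case_id")
  if (length(ids) != nrow(truth) || !setequal(ids, truth$case_id)) {
    stop_readiff("cases and truth must describe the same case set",
                 "readiff_input_error")
  }
  d <- truth$latent_difficulty[match(ids, truth$case_id)]
  alpha <- config$error_link_intercept
  beta <- config$error_link_slope
  with_seed(substream_seed(config$seed, "panel"), {
    bias <- rnorm(config$n_readers, 0, config$reader_bias_sd)
    out <- vector("list", config$n_readers * length(cases))
    k <- 0
    for (r in seq_len(config$n_readers)) {
      rid <- sprintf("reader%02d", r)
      for (ci in seq_along(cases)) {
        cs <- cases[[ci]]
        p_err <- plogis(alpha + beta * d[ci] + bias[r])
        err <- runif(1) < p_err
        rating <- NA_integer_; view <- NA_character_
        x <- NA_real_; y <- NA_real_
        if (!cs$cancer) {
          rating <- if (err) sample(3:5, 1) else sample(1:2, 1)
        } else {
          lesion_views <- names(cs$lesion$views)
          if (!err) {
            rating <- sample(3:5, 1)
            view <- sample(lesion_views, 1)
            pos <- cs$lesion$views[[view]]
            jit <- runif_disc(0.3 * config$loc_radius)
            y <- pos[1] + jit[1]; x <- pos[2] + jit[2]
          } else if (runif(1) < config$loc_error_frac) {
            rating <- sample(3:5, 1)
            view <- sample(lesion_views, 1)
            pos <- cs$lesion$views[[view]]
            disp <- runif_annulus(config$loc_radius, 2 * config$loc_radius)
            y <- pos[1] + disp[1]; x <- pos[2] + disp[2]
          } else {
            rating <- sample(1:2, 1)
          }
        }
        k <- k + 1
        out[[k]] <- data.frame(reader_id = rid, case_id = cs$case_id,
                               rating = rating, view = view, x = x, y = y)
      }
    }
    do.call(rbind, out)
  })
}

runif_disc <- function(rmax) {
  a <- runif(1, 0, 2 * pi)
  r <- rmax * sqrt(runif(1))
  c(r * sin(a), r * cos(a))
}

runif_annulus <- function(rmin, rmax) {
  a <- runif(1, 0, 2 * pi)
  r <- sqrt(runif(1, rmin^2, rmax^2))
  # open at rmin: resample the degenerate boundary draw
  if (r <= rmin) r <- rmin + 1e-6
  c(r * sin(a), r * cos(a))
}

#' Write a cohort and reader responses to disk
#'
#' Views are written as 16-bit PNG (`{case}_{view}.png`), the truth and
#' lesion tables and responses as CSV, and a manifest JSON recording the
#' configuration, seed, intensity scale and a config hash.
#'
#' @param cohort a `synthetic_cohort`.
#' @param responses reader-response data frame (optional).
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, responses = NULL, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(vapply(cohort$cases, function(cs)
    max(vapply(cs$views, max, 0)), 0))
  files <- character(0)
  for (cs in cohort$cases) {
    for (tag in names(cs$views)) {
      f <- file.path(dir, sprintf("%s_%s.png", cs$case_id, tag))
      write_view(cs$views[[tag]] / scale, f)
      files <- c(files, f)
    }
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(cohort$lesions)) {
    utils::write.csv(cohort$lesions, file.path(dir, "lesions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(responses)) {
    utils::write.csv(responses, file.path(dir, "responses.csv"),
                     row.names = FALSE)
  }
  manifest <- list(config = unclass(cohort$config),
                   config_hash = config_hash(unclass(cohort$config)),
                   intensity_scale = scale,
                   n_views = length(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read and write single views
#'
#' Views are stored as 16-bit grayscale PNG (written by a minimal in-package
#' encoder: none of the installed readers' companion writers emit 16-bit
#' PNG); in memory they are numeric matrices indexed `[row, col]` with row 1
#' at the top.
#' @param view numeric matrix in `[0, 1]`.
#' @param path PNG file path.
#' @export
write_view <- function(view, path) {
  stopifnot(is.matrix(view), min(view) >= 0, max(view) <= 1)
  m <- round(view * 65535)
  hi <- m %/% 256; lo <- m %% 256
  scan <- vapply(seq_len(nrow(view)), function(r) {
    c(0, as.vector(rbind(hi[r, ], lo[r, ])))
  }, numeric(1 + 2 * ncol(view)))
  idat <- memCompress(as.raw(as.vector(scan)), "gzip")  # zlib stream
  ihdr <- as.raw(c(int_be(ncol(view)), int_be(nrow(view)),
                   16, 0, 0, 0, 0))  # bit depth 16, grayscale
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

int_be <- function(x) c(x %/% 2^24, x %/% 2^16 %% 256, x %/% 256 %% 256,
                        x %% 256)

png_chunk <- function(type, data) {
  body <- c(as.raw(utf8ToInt(type)), data)
  as.raw(c(int_be(length(data)), as.integer(body), int_be(crc32(body))))
}

# CRC-32 (polynomial 0xEDB88320), table-driven; R's bitwise ops treat
# integers as 32-bit two's-complement patterns, which is what we need.
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      poly <- -306674912L  # 0xEDB88320
      tab <<- vapply(0:255, function(i) {
        cr <- as.integer(i)
        for (k in 1:8) {
          cr <- if (bitwAnd(cr, 1L) != 0L) {
            bitwXor(poly, bitwShiftR(cr, 1L))
          } else bitwShiftR(cr, 1L)
        }
        cr
      }, integer(1))
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

#' @rdname write_view
#' @export
read_view <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
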