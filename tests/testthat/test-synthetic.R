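# Synthetic cohort generator: determinism, geometry, difficulty link.

test_that("case generation is deterministic and respects geometry", {
  cfg <- synthetic_config(n_normal = 1, n_cancer = 1, image_size = 96,
                          blob_count_range = c(10, 20), seed = 5)
  a <- generate_case(cfg, 2)
  b <- generate_case(cfg, 2)
  expect_identical(a$views, b$views)
  expect_identical(a$meta, b$meta)
  other <- generate_case(cfg, 1)
  expect_false(identical(a$views$LCC, other$views$LCC))

  # lesion lies inside the silhouette of both lesion-side views
  expect_true(a$cancer)
  side <- a$lesion$side
  for (tag in paste0(side, c("CC", "MLO"))) {
    pos <- a$lesion$views[[tag]]
    sil <- a$silhouette[[if (side == "L") "left" else "right"]]
    expect_true(sil[pos[1], pos[2]])
  }
  # views are dark outside the breast
  expect_equal(max(a$views$LCC[!a$silhouette$left]), 0)
})

test_that("degenerate blob width interval yields zero variance of the mean width", {
  cfg <- synthetic_config(n_normal = 50, n_cancer = 1, image_size = 64,
                          blob_count_range = c(8, 12),
                          blob_sigma_range = c(4, 4), seed = 3)
  m <- vapply(1:50, function(i) mean(generate_case(cfg, i)$meta$sigmas), 0)
  expect_equal(var(m), 0)
  d <- vapply(1:50, function(i) generate_case(cfg, i)$meta$latent_difficulty, 0)
  expect_true(all(d == 0))
})

test_that("config validation rejects bad inputs", {
  expect_error(synthetic_config(image_size = 32), class = "readiff_config_error")
  expect_error(synthetic_config(n_readers = 0), class = "readiff_config_error")
  expect_error(synthetic_config(blob_sigma_range = c(5, 2)),
               class = "readiff_config_error")
})

test_that("texture-independent errors match the intercept (beta = 0)", {
  stub <- stub_cohort(50, seed = 2)
  cfg <- synthetic_config(n_normal = 50, n_cancer = 1, n_readers = 100,
                          error_link_intercept = qlogis(0.3),
                          error_link_slope = 0, reader_bias_sd = 0, seed = 9)
  resp <- simulate_reader_panel(stub$cases, stub$truth, cfg)
  err_rate <- mean(resp$rating >= 3)
  se <- sqrt(0.3 * 0.7 / nrow(resp))
  expect_lt(abs(err_rate - 0.3), 3 * se)
  # texture independence: no association with latent difficulty
  prop <- tapply(resp$rating >= 3, resp$case_id, mean)
  expect_lt(abs(cor(stub$truth$latent_difficulty,
                    prop[stub$truth$case_id], method = "spearman")), 0.35)
})

test_that("strong texture coupling orders per-case error proportions", {
  stub <- stub_cohort(50, seed = 4)
  cfg <- synthetic_config(n_normal = 50, n_cancer = 1, n_readers = 30,
                          error_link_slope = 5, reader_bias_sd = 0.5, seed = 21)
  resp <- simulate_reader_panel(stub$cases, stub$truth, cfg)
  prop <- tapply(resp$rating >= 3, resp$case_id, mean)
  expect_gt(cor(stub$truth$latent_difficulty, prop[stub$truth$case_id],
                method = "spearman"), 0.8)
})

test_that("cancer-case responses honour the error taxonomy", {
  stub <- stub_cohort(40, cancer = TRUE, seed = 6)
  cfg <- synthetic_config(n_normal = 1, n_cancer = 40, n_readers = 20,
                          error_link_intercept = 0, error_link_slope = 0,
                          reader_bias_sd = 0, loc_error_frac = 0.5,
                          image_size = 192, seed = 31)
  resp <- simulate_reader_panel(stub$cases, stub$truth, cfg)
  # misses carry no annotation; positives always carry one
  neg <- resp$rating <= 2
  expect_true(all(is.na(resp$x[neg])))
  expect_true(all(!is.na(resp$x[!neg])))
  # correct localizations within radius; localization errors beyond it
  lesions <- data.frame(case_id = rep(stub$truth$case_id, each = 2),
                        view = rep(c("LCC", "LMLO"), 40),
                        x = rep(c(50, 40), 40), y = rep(c(50, 60), 40))
  pos <- resp[!neg, ]
  d <- vapply(seq_len(nrow(pos)), function(i) {
    les <- lesions[lesions$case_id == pos$case_id[i] &
                     lesions$view == pos$view[i], ]
    sqrt((les$x - pos$x[i])^2 + (les$y - pos$y[i])^2)
  }, 0)
  r <- cfg$loc_radius
  expect_true(all(d <= r | (d > r & d <= 2 * r + 1e-6)))
  expect_true(any(d > r))   # some localization errors occurred
  expect_true(any(d <= r))  # and some correct localizations
})

test_that("mismatched case and truth tables are rejected", {
  stub <- stub_cohort(5, seed = 1)
  cfg <- synthetic_config(n_normal = 5, n_cancer = 1, seed = 1)
  expect_error(simulate_reader_panel(stub$cases, stub$truth[1:3, ], cfg),
               class = "readiff_input_error")
})

test_that("cohort files round-trip through 16-bit PNG", {
  cfg <- synthetic_config(n_normal = 1, n_cancer = 1, image_size = 64,
                          blob_count_range = c(5, 8), seed = 13)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  man <- write_cohort(cohort, responses = NULL, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  v <- read_view(file.path(dir, "case001_LCC.png")) * man$intensity_scale
  expect_lt(max(abs(v - cohort$cases[[1]]$views$LCC)),
            man$intensity_scale / 65535 * 1.01)
})
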