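# Feature bank: quantization, per-family worked examples, registry contract.

test_that("quantization bins correctly and rejects constants", {
  roi <- roi_image(matrix(0:31, 4, 8))
  q <- quantize(roi, Ng = 32)
  expect_equal(as.vector(q$levels), 0:31)
  q2 <- quantize(roi_image(matrix(c(0, 10, 0, 10), 2, 2)), Ng = 2)
  expect_equal(sort(unique(as.vector(q2$levels))), c(0, 1))
  expect_error(quantize(const_roi()), class = "readiff_quantization_error")
  # uniform random patch occupies all 8 levels with >= 1% frequency
  set.seed(1)
  q3 <- quantize(roi_image(matrix(runif(128 * 128), 128, 128)), Ng = 8)
  frq <- tabulate(q3$levels + 1, 8) / (128 * 128)
  expect_true(all(frq >= 0.01))
})

test_that("histogram statistics match hand computations", {
  f <- histogram_features(roi_image(matrix(1:4, 2, 2)))
  expect_equal(f[["hist_mean"]], 2.5)
  expect_equal(f[["hist_median"]], 2.5)
  expect_equal(f[["hist_p25"]], 1.75)   # type-7 percentile rule
  expect_equal(f[["hist_p75"]], 3.25)
  expect_equal(f[["hist_iqr"]], 1.5)
  expect_equal(f[["hist_range"]], 3)

  fc <- histogram_features(const_roi(4))
  expect_equal(fc[["hist_sd"]], 0)
  expect_equal(fc[["hist_entropy"]], 0)
  expect_equal(fc[["hist_uniformity"]], 1)

  sym <- histogram_features(roi_image(matrix(c(-3, -1, 0, 0, 1, 3), 2, 3)))
  expect_lt(abs(sym[["hist_skewness"]]), 1e-12)
})

test_that("GLCM worked examples hold", {
  chk <- quantized_roi <- readiff:::quantized_roi(
    matrix(c(0L, 1L, 1L, 0L), 2, 2), matrix(TRUE, 2, 2), 2)
  p <- readiff:::glcm_matrix(chk, c(0L, 1L))
  expect_equal(p[1, 2] + p[2, 1], 1)  # all mass on (0,1)/(1,0)
  f <- glcm_features(chk)
  expect_equal(f[["glcm_contrast_d0"]], 1)

  const_q <- readiff:::quantized_roi(matrix(0L, 6, 6), matrix(TRUE, 6, 6), 4)
  fc <- glcm_features(const_q)
  for (o in c("d0", "d45", "d90", "d135")) {
    expect_equal(fc[[paste0("glcm_contrast_", o)]], 0)
    expect_equal(fc[[paste0("glcm_max_prob_", o)]], 1)
  }
})

test_that("GLCM offset set is closed under transpose (0<->90, 45<->135 fixed)", {
  for (s in 1:5) {
    q <- quantize(rand_roi(16, 16, seed = 100 + s), Ng = 8)
    qt <- readiff:::quantized_roi(t(q$levels), t(q$valid), q$Ng)
    f <- glcm_features(q); ft <- glcm_features(qt)
    for (st in readiff:::glcm_stat_names()) {
      expect_equal(ft[[paste0("glcm_", st, "_d0")]],
                   f[[paste0("glcm_", st, "_d90")]])
      expect_equal(ft[[paste0("glcm_", st, "_d90")]],
                   f[[paste0("glcm_", st, "_d0")]])
      expect_equal(ft[[paste0("glcm_", st, "_d45")]],
                   f[[paste0("glcm_", st, "_d45")]])
      expect_equal(ft[[paste0("glcm_", st, "_d135")]],
                   f[[paste0("glcm_", st, "_d135")]])
    }
  }
})

test_that("run extraction matches hand enumeration", {
  q <- readiff:::quantized_roi(matrix(c(0L, 0L, 1L, 1L, 1L), 1, 5),
                               matrix(TRUE, 1, 5), 2)
  runs <- readiff:::extract_runs(q$levels, q$valid, "d0")
  expect_equal(runs$level, c(0L, 1L))
  expect_equal(runs$length, c(2L, 3L))
  # RP along rows for this single-line patch: 2 runs over 5 pixels
  expect_equal(length(runs$length) / sum(q$valid), 2 / 5)
  # invalid pixels break runs
  q2 <- readiff:::quantized_roi(matrix(c(1L, 1L, 0L, 1L, 1L), 1, 5),
                                matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE), 1, 5), 2)
  runs2 <- readiff:::extract_runs(q2$levels, q2$valid, "d0")
  expect_equal(runs2$length, c(2L, 2L))
})

test_that("NGTDM and Laws respond correctly to flat input", {
  const_q <- readiff:::quantized_roi(matrix(3L, 10, 10), matrix(TRUE, 10, 10), 8)
  f <- ngtdm_features(const_q)
  expect_equal(f[["ngtdm_contrast_n3"]], 0)
  expect_equal(f[["ngtdm_contrast_n5"]], 0)
  expect_equal(f[["ngtdm_contrast_n7"]], 0)

  fl <- laws_features(const_roi(2, 16, 16))
  expect_equal(fl[["laws_E5E5_mean"]], 0)
  expect_equal(fl[["laws_E5E5_sd"]], 0)
})

test_that("fractal dimension separates solid patches from sparse dots", {
  fd_solid <- fractal_features(const_roi(1, 48, 48))[["fractal_dimension"]]
  expect_lt(abs(fd_solid - 2), 0.1)
  set.seed(8)
  dots <- matrix(0, 48, 48)
  dots[cbind(sample(48, 12), sample(48, 12))] <- 1
  fd_dots <- fractal_features(roi_image(dots))[["fractal_dimension"]]
  expect_lt(fd_dots, 2)
})

test_that("transform features behave as filter theory predicts", {
  # constant input: all bar/edge MR8 energies are zero
  fc <- transform_features(const_roi(1, 64, 64))
  for (nm in c(paste0("rfs_bar_s", 1:3), paste0("rfs_edge_s", 1:3))) {
    expect_lt(abs(fc[[nm]]), 1e-20)
  }
  # white noise: same-frequency Gabor responses are orientation-isotropic
  # (Monte-Carlo average over 10 independent patches, fixed seed)
  set.seed(42)
  gmat <- sapply(1:10, function(i) {
    f <- transform_features(roi_image(matrix(rnorm(96 * 96), 96, 96)))
    f[readiff:::gabor_feature_names()]
  })
  gbar <- rowMeans(gmat)
  for (f in 1:2) {
    g <- gbar[paste0("gabor_f", f, "_o", c(0, 60, 120))]
    expect_lt((max(g) - min(g)) / mean(g), 0.10)
  }
  # horizontal sinusoid at the tuned wavelength: orientation 0 wins
  cols <- matrix(rep(1:64, each = 64), 64, 64)
  sin_img <- sin(2 * pi * cols / 6)
  fs <- transform_features(roi_image(sin_img))
  g <- fs[readiff:::gabor_feature_names()]
  expect_equal(names(which.max(g)), "gabor_f2_o0")
  # too-small ROI errors
  expect_error(transform_features(const_roi(1, 10, 10)),
               class = "readiff_input_error")
})

test_that("the full bank is deterministic, complete and padding-invariant", {
  fx <- demo_case(image_size = 192, seed = 7, index = 1)
  roi <- preprocess_view(fx$case$views$LCC, "LCC")$rois$square
  f1 <- extract_all(roi)
  f2 <- extract_all(roi)
  expect_identical(f1, f2)
  expect_length(f1, 203)
  expect_true(all(is.finite(f1)))
  reg <- feature_registry()
  expect_identical(names(f1), reg$name)

  # padding with invalid pixels changes nothing
  pad <- roi_image(rbind(0, cbind(0, roi$pixels, 0), 0),
                   valid = rbind(FALSE, cbind(FALSE, roi$valid, FALSE), FALSE),
                   roi_kind = roi$roi_kind)
  expect_equal(extract_all(pad), f1, ignore_attr = TRUE)
})

test_that("family errors carry the family name", {
  err <- tryCatch(extract_all(const_roi(1, 64, 64)), error = function(e) e)
  expect_s3_class(err, "readiff_quantization_error")
  expect_match(conditionMessage(err), "quantize")
})
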