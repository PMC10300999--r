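# Segmentation, pectoral removal, ROI delineation, normalization.

test_that("segmentation recovers the generated silhouette", {
  fx <- demo_case(image_size = 128, seed = 11, index = 1)
  cs <- fx$case
  iou <- function(a, b) sum(a & b) / sum(a | b)
  bm <- segment_breast(cs$views$LCC)
  expect_gte(iou(bm$mask, cs$silhouette$left), 0.98)
  # right views after mirroring
  v <- orient_chest_left(cs$views$RCC, "RCC")
  bm_r <- segment_breast(v)
  expect_gte(iou(bm_r$mask, cs$silhouette$left), 0.98)
  # nipple is the contour point farthest from the chest wall
  expect_equal(bm$nipple[2], max(which(bm$mask, arr.ind = TRUE)[, 2]))
})

test_that("segmentation is idempotent and fails on degenerate input", {
  fx <- demo_case(image_size = 128, seed = 11, index = 1)
  bm <- segment_breast(fx$case$views$LCC)
  again <- segment_breast(bm$mask * 1)
  expect_identical(again$mask, bm$mask)
  expect_error(segment_breast(matrix(0, 64, 64)),
               class = "readiff_segmentation_error")
  expect_error(segment_breast(matrix(2.5, 64, 64)),
               class = "readiff_segmentation_error")
})

test_that("only the largest foreground component is retained", {
  img <- matrix(0, 80, 80)
  img[10:40, 10:40] <- 1   # 31x31 blob
  img[55:70, 55:70] <- 1   # 16x16 blob
  bm <- segment_breast(img)
  expect_true(all(bm$mask[12:38, 12:38]))
  expect_false(any(bm$mask[55:70, 55:70]))
})

test_that("pectoral wedge is removed on MLO views, and only there", {
  fx <- demo_case(image_size = 192, seed = 7, index = 1)
  cs <- fx$case
  v <- cs$views$LMLO
  bm <- segment_breast(v)
  out <- remove_pectoral(v, bm, "LMLO")
  expect_false(is.null(out$pectoral_line))
  w <- cs$wedges$LMLO
  expect_gte(sum(w & !out$mask) / sum(w), 0.95)
  nonwedge <- cs$silhouette$left & !w & bm$mask
  expect_lte(sum(nonwedge & !out$mask) / sum(nonwedge), 0.02)
  # pectoral-side invariant: no remaining mask pixel on the chest side
  expect_error(remove_pectoral(v, bm, "LCC"), class = "readiff_usage_error")
})

test_that("no line is claimed when there is no wedge or the angle is extreme", {
  fx <- demo_case(image_size = 192, seed = 7, index = 1)
  cs <- fx$case
  bm_cc <- segment_breast(cs$views$LCC)
  out <- remove_pectoral(cs$views$LCC, bm_cc, "LMLO")
  expect_null(out$pectoral_line)
  expect_identical(out$mask, bm_cc$mask)

  # wedge at ~5 degrees from vertical: outside the accepted 10-80 band
  size <- 192
  sil <- readiff:::breast_silhouette(size, "left")
  img <- matrix(0, size, size); img[sil] <- 0.6
  w <- readiff:::pectoral_wedge(size, c_top = 10, r_bot = 115, sil)
  img[w] <- img[w] + 0.6
  bm <- segment_breast(img)
  out2 <- remove_pectoral(img, bm, "LMLO")
  expect_null(out2$pectoral_line)
  expect_identical(out2$mask, bm$mask)
})

test_that("largest inscribed square matches brute force on random masks", {
  for (s in 1:50) {
    set.seed(s)
    nr <- sample(10:40, 1); nc <- sample(10:40, 1)
    mask <- matrix(runif(nr * nc) < 0.75, nr, nc)
    got <- readiff:::largest_inscribed_square(mask)
    want <- oracle_largest_square(mask)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$side, want$side, info = paste("seed", s))
      expect_equal(got$top, want$top, info = paste("seed", s))
      expect_equal(got$left, want$left, info = paste("seed", s))
    }
  }
})

test_that("ROI delineation honours its contracts", {
  # full-rectangle mask: square side = min(h, w)
  view <- matrix(runif(20 * 31), 20, 31)
  bm <- readiff:::new_breast_mask(matrix(TRUE, 20, 31))
  rois <- extract_rois(view, bm)
  expect_equal(dim(rois$square$pixels), c(20, 20))
  expect_equal(dim(rois$whole$pixels), c(20, 31))
  # retroareolar pixels are a subset of the mask
  fx <- demo_case(image_size = 128, seed = 11, index = 1)
  pre <- preprocess_view(fx$case$views$LCC, "LCC", normalize = FALSE)
  ra <- pre$rois$retroareolar
  b <- ra$bbox
  expect_identical(ra$valid, pre$mask$mask[b[1]:b[2], b[3]:b[4]])
  # mask too small for an 8-px square
  tiny <- readiff:::new_breast_mask(rbind(matrix(TRUE, 5, 30),
                                          matrix(FALSE, 25, 30)))
  expect_error(extract_rois(matrix(0.5, 30, 30), tiny),
               class = "readiff_roi_error")
})

test_that("z-scoring matches hand computation and validates input", {
  roi <- roi_image(matrix(c(10, 10, 20, 20), 2, 2))
  z <- zscore_roi(roi)
  expect_equal(sort(unique(as.vector(z$pixels))), c(-1, 1))
  expect_true(z$normalized)

  fx <- demo_case(image_size = 128, seed = 11, index = 1)
  pre <- preprocess_view(fx$case$views$LCC, "LCC", normalize = TRUE)
  for (roi in pre$rois) {
    v <- roi$pixels[roi$valid]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  }
  expect_error(zscore_roi(const_roi()), class = "readiff_normalization_error")
  expect_error(zscore_roi(roi_image(matrix(1), valid = matrix(TRUE))),
               class = "readiff_normalization_error")
})

test_that("the z-scored feature pipeline is affine-invariant", {
  fx <- demo_case(image_size = 192, seed = 7, index = 1)
  v <- fx$case$views$LCC
  f1 <- extract_all(preprocess_view(v, "LCC")$rois$square)
  f2 <- extract_all(preprocess_view(3.2 * v + 10, "LCC")$rois$square)
  expect_equal(f1, f2, tolerance = 1e-6)
})
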