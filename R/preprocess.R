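# Breast segmentation, pectoral-muscle removal, ROI delineation and
# normalization. All functions assume chest-wall-left orientation (use
# orient_chest_left() on right-sided views first) and matrices indexed
# [row, col], 1-based, with inclusive bounding boxes.

as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

largest_component <- function(mask) {
  lab <- from_ebi(EBImage::bwlabel(as_ebi(mask * 1)))
  tab <- tabulate(lab[lab > 0])
  if (!length(tab)) return(mask & FALSE)
  lab == which.max(tab)
}

#' Segment the breast region from a mammographic view
#'
#' Otsu threshold, retain the largest connected foreground component, open
#' with a disc structuring element, fill holes. The nipple point is taken as
#' the breast-contour point farthest from the chest wall (largest column in
#' chest-left orientation).
#'
#' @param view numeric matrix, single-channel.
#' @param opening_radius disc radius in pixels for morphological opening.
#' @return A `breast_mask`: list with `mask` (logical matrix, one connected
#'   component), `pectoral_line` (NULL until [remove_pectoral()] detects
#'   one) and `nipple` (`c(row, col)`).
#' @export
segment_breast <- function(view, opening_radius = 5) {
  if (!is.matrix(view) || !is.numeric(view)) {
    stop_readiff("view must be a numeric matrix", "readiff_input_error")
  }
  rng <- range(view, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] >= rng[2]) {
    stop_readiff("blank or constant image: cannot segment",
                 "readiff_segmentation_error")
  }
  v <- (view - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(as_ebi(v), range = c(0, 1), levels = 256)
  bw <- v > th
  if (!any(bw)) {
    stop_readiff("thresholding produced an empty foreground",
                 "readiff_segmentation_error")
  }
  bw <- largest_component(bw)
  brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
  bw <- from_ebi(EBImage::opening(as_ebi(bw * 1), brush)) > 0.5
  if (!any(bw)) {
    stop_readiff("foreground vanished under morphological opening",
                 "readiff_segmentation_error")
  }
  bw <- largest_component(bw)
  bw <- from_ebi(EBImage::fillHull(as_ebi(bw * 1))) > 0.5
  new_breast_mask(bw)
}

new_breast_mask <- function(mask, pectoral_line = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  cmax <- max(idx[, 2])
  rows_at <- idx[idx[, 2] == cmax, 1]
  nipple <- c(round(stats::median(rows_at)), cmax)
  structure(list(mask = mask, pectoral_line = pectoral_line, nipple = nipple),
            class = "breast_mask")
}

#' Remove the pectoral muscle from an MLO view's breast mask
#'
#' Computes a gradient edge map restricted to the chest-wall upper quadrant
#' of the mask, runs a straight-line Hough transform, and accepts the
#' highest-vote line whose inclination from vertical lies in `angle_range`
#' degrees, provided it clears the vote threshold. Mask pixels on the
#' chest-wall side of the line are zeroed. If no line qualifies the mask is
#' returned unchanged with `pectoral_line` absent.
#'
#' @param view the (chest-left oriented) MLO view.
#' @param bmask a `breast_mask` from [segment_breast()].
#' @param view_tag must be an MLO tag.
#' @param angle_range accepted inclination from vertical, degrees.
#' @param vote_frac vote threshold as a fraction of the smaller image side.
#' @return A `breast_mask` with the wedge removed and `pectoral_line` set to
#'   a 2x2 matrix of endpoints (rows `c(row, col)`), or the input mask
#'   unchanged when no line is detected.
#' @export
remove_pectoral <- function(view, bmask, view_tag,
                            angle_range = c(10, 80), vote_frac = 0.2) {
  if (!is_mlo(view_tag)) {
    stop_readiff("remove_pectoral applies to MLO views only",
                 "readiff_usage_error")
  }
  stopifnot(inherits(bmask, "breast_mask"))
  mask <- bmask$mask
  nr <- nrow(view); nc <- ncol(view)

  sob <- sobel_magnitude(view)
  quad <- matrix(FALSE, nr, nc)
  quad[seq_len(ceiling(nr / 2)), seq_len(ceiling(nc / 2))] <- TRUE
  # keep clear of the breast/background border, whose step response would
  # otherwise dominate the edge map
  interior <- box_sum(mask * 1, 3) == 49
  region <- quad & mask & interior
  mag <- sob[region]
  if (!length(mag) || max(mag) <= 0) return(bmask)
  th <- stats::quantile(mag, 0.98)
  edge <- region & (sob >= th) & (sob > 0)
  pts <- which(edge, arr.ind = TRUE)
  if (nrow(pts) < 10) return(bmask)

  thetas <- seq(angle_range[1], angle_range[2], by = 1) * pi / 180
  rho_bin <- 2
  vote_min <- vote_frac * min(nr, nc)
  best <- list(votes = 0)
  for (th_i in thetas) {
    rho <- pts[, 2] * cos(th_i) + pts[, 1] * sin(th_i)
    bins <- round(rho / rho_bin)
    tab <- table(bins)
    v <- max(tab)
    if (v > best$votes) {
      best <- list(votes = v, theta = th_i,
                   rho = as.numeric(names(tab)[which.max(tab)]) * rho_bin)
    }
  }
  if (best$votes < vote_min) return(bmask)

  # refine with a total-least-squares fit to the winning bin's inliers and
  # re-check the inclination: a line just outside the accepted band can still
  # light up an edge-of-band accumulator cell
  rho_pt <- pts[, 2] * cos(best$theta) + pts[, 1] * sin(best$theta)
  inl <- pts[abs(rho_pt - best$rho) <= 2 * rho_bin, , drop = FALSE]
  if (nrow(inl) < 10) return(bmask)
  xy <- cbind(inl[, 2], inl[, 1])  # (col, row)
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  dirv <- ev$vectors[, 1]          # line direction
  incl <- atan2(abs(dirv[1]), abs(dirv[2])) * 180 / pi  # from vertical
  if (incl < angle_range[1] || incl > angle_range[2]) return(bmask)
  nrm <- c(-dirv[2], dirv[1])      # unit normal in (col, row)
  if (nrm[1] < 0) nrm <- -nrm      # cos(theta) >= 0 for theta in (0, 90)
  best$theta <- atan2(nrm[2], nrm[1])
  best$rho <- sum(nrm * colMeans(xy))

  ct <- cos(best$theta); st <- sin(best$theta); rho <- best$rho
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rows <- matrix(seq_len(nr), nr, nc)
  s <- cols * ct + rows * st - rho
  s0 <- ct + st - rho  # top-left corner is on the chest-wall side
  removed <- mask & (sign(s) == sign(s0))
  mask[removed] <- FALSE
  if (!any(mask)) return(bmask)
  mask <- largest_component(mask)

  # endpoints: intersections with the top and left image borders
  p_top <- c(1, (rho - st) / ct)
  p_left <- c((rho - ct) / st, 1)
  line <- rbind(p_top, p_left)
  out <- new_breast_mask(mask, pectoral_line = line)
  out$nipple <- bmask$nipple
  out
}

sobel_magnitude <- function(x) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2_same(x, kx)
  gy <- conv2_same(x, t(kx))
  sqrt(gx^2 + gy^2)
}

#' ROI patch container
#'
#' A pixel patch cut from a view, with a validity mask marking in-breast
#' pixels. All feature statistics are computed over valid pixels only;
#' texture matrices treat invalid pixels as invalid neighbours.
#'
#' @param pixels numeric matrix.
#' @param valid logical matrix, same shape (default all valid).
#' @param roi_kind one of "square", "retroareolar", "whole".
#' @param view_tag view of origin (or NA).
#' @param bbox inclusive `c(row1, row2, col1, col2)` in view coordinates.
#' @param normalized logical flag set by [zscore_roi()].
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(pixels, valid = NULL, roi_kind = "square",
                      view_tag = NA_character_, bbox = NULL,
                      normalized = FALSE) {
  stopifnot(is.matrix(pixels))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pixels), ncol(pixels))
  stopifnot(identical(dim(valid), dim(pixels)))
  structure(list(pixels = pixels, valid = valid, roi_kind = roi_kind,
                 view_tag = view_tag, bbox = bbox, normalized = normalized),
            class = "roi_image")
}

roi_values <- function(roi) roi$pixels[roi$valid]

# Largest axis-aligned square of TRUE cells: binary search on the side using
# summed-area-table window sums; ties broken by smallest top-left row, then
# column.
largest_inscribed_square <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  sat <- rbind(0, cbind(0, t(apply(apply(mask * 1, 2, cumsum), 1, cumsum))))
  win_full <- function(s) {
    if (s > nr || s > nc) return(NULL)
    i <- seq_len(nr - s + 1); j <- seq_len(nc - s + 1)
    sums <- sat[i + s, j + s, drop = FALSE] - sat[i, j + s, drop = FALSE] -
      sat[i + s, j, drop = FALSE] + sat[i, j, drop = FALSE]
    sums == s * s
  }
  lo <- 0; hi <- min(nr, nc)
  while (lo < hi) {
    mid <- (lo + hi + 1) %/% 2
    if (any(win_full(mid))) lo <- mid else hi <- mid - 1
  }
  if (lo == 0) return(NULL)
  hits <- which(win_full(lo), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(side = lo, top = unname(hits[1, 1]), left = unname(hits[1, 2]))
}

#' Delineate the three regions of interest
#'
#' Square: the largest axis-aligned square fully inside the mask.
#' Retroareolar: a square of side `ra_frac` times the breast depth (the
#' horizontal extent of the mask), centred on the nipple point, clipped to
#' the image; out-of-mask pixels are marked invalid. Whole: the mask
#' bounding-box crop with out-of-mask pixels invalid.
#'
#' @param view numeric matrix (chest-left oriented).
#' @param bmask a `breast_mask`.
#' @param view_tag view tag carried into the ROIs.
#' @param ra_frac retroareolar side as a fraction of breast depth.
#' @return Named list of three `roi_image`s: `square`, `retroareolar`,
#'   `whole`.
#' @export
extract_rois <- function(view, bmask, view_tag = NA_character_,
                         ra_frac = 0.25) {
  stopifnot(inherits(bmask, "breast_mask"))
  mask <- bmask$mask
  if (!any(mask)) stop_readiff("empty mask", "readiff_roi_error")

  sq <- largest_inscribed_square(mask)
  if (is.null(sq) || sq$side < 8) {
    stop_readiff("mask too small to contain an 8-pixel square",
                 "readiff_roi_error")
  }
  rs <- sq$top:(sq$top + sq$side - 1)
  cs <- sq$left:(sq$left + sq$side - 1)
  roi_sq <- roi_image(view[rs, cs], roi_kind = "square", view_tag = view_tag,
                      bbox = c(rs[1], rs[length(rs)], cs[1], cs[length(cs)]))

  idx <- which(mask, arr.ind = TRUE)
  depth <- diff(range(idx[, 2])) + 1
  side <- max(8, round(ra_frac * depth))
  half <- side %/% 2
  r1 <- max(1, bmask$nipple[1] - half); r2 <- min(nrow(mask), r1 + side - 1)
  c1 <- max(1, bmask$nipple[2] - side + 1); c2 <- min(ncol(mask), c1 + side - 1)
  # centre on the nipple but keep the patch inside the image and biased into
  # the breast (the nipple sits on the contour, so extend toward the chest)
  roi_ra <- roi_image(view[r1:r2, c1:c2], valid = mask[r1:r2, c1:c2],
                      roi_kind = "retroareolar", view_tag = view_tag,
                      bbox = c(r1, r2, c1, c2))

  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  roi_wh <- roi_image(view[rr[1]:rr[2], cr[1]:cr[2]],
                      valid = mask[rr[1]:rr[2], cr[1]:cr[2]],
                      roi_kind = "whole", view_tag = view_tag,
                      bbox = c(rr[1], rr[2], cr[1], cr[2]))

  list(square = roi_sq, retroareolar = roi_ra, whole = roi_wh)
}

#' Z-score normalize an ROI
#'
#' Centres and scales the patch by the mean and standard deviation of its
#' valid pixels (population SD, 1/n denominator, so a two-valued patch
#' {10, 10, 20, 20} maps exactly to -1/+1). The input ROI is unchanged;
#' callers keep the original when both tracks are analysed.
#'
#' @param roi a `roi_image`.
#' @return A normalized `roi_image` (`normalized = TRUE`).
#' @export
zscore_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi_values(roi)
  if (length(v) < 2) {
    stop_readiff("need at least 2 valid pixels to normalize",
                 "readiff_normalization_error")
  }
  s <- sqrt(mean((v - mean(v))^2))
  if (!is.finite(s) || s < 1e-12) {
    stop_readiff("zero variance: cannot z-score", "readiff_normalization_error")
  }
  out <- roi
  out$pixels <- (roi$pixels - mean(v)) / s
  out$pixels[!roi$valid] <- 0
  out$normalized <- TRUE
  out
}

#' Preprocess one view end to end
#'
#' Orients the view chest-left, segments the breast, removes the pectoral
#' muscle on MLO views, and extracts the three ROIs, optionally z-scored.
#'
#' @param view numeric matrix.
#' @param view_tag one of `view_tags()`.
#' @param normalize z-score each ROI.
#' @param opening_radius,ra_frac passed through.
#' @return List with `mask` (`breast_mask`) and `rois` (list of three
#'   `roi_image`s).
#' @export
preprocess_view <- function(view, view_tag, normalize = TRUE,
                            opening_radius = 5, ra_frac = 0.25) {
  v <- orient_chest_left(view, view_tag)
  bm <- segment_breast(v, opening_radius = opening_radius)
  if (is_mlo(view_tag)) bm <- remove_pectoral(v, bm, view_tag)
  rois <- extract_rois(v, bm, view_tag = view_tag, ra_frac = ra_frac)
  if (normalize) rois <- lapply(rois, zscore_roi)
  list(mask = bm, rois = rois)
}
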