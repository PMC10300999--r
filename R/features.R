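#' The 203-feature registry
#'
#' Fixed, ordered registry of the full radiomic feature bank: 28 histogram,
#' 88 GLCM, 7 GLRLM, 6 GLSM, 15 GLDS, 15 NGTDM, 8 SFM, 18 Laws, 2 fractal,
#' 6 Gabor, 8 RFS/MR8 and 2 Fourier features. Names and order are stable API;
#' [extract_all()] returns its vector in exactly this order.
#'
#' @return Data frame with columns `name` and `family` (203 rows).
#' @export
feature_registry <- function() {
  fam <- list(
    histogram = hist_feature_names(),
    GLCM = glcm_feature_names(),
    GLRLM = glrlm_feature_names(),
    GLSM = glsm_feature_names(),
    GLDS = glds_feature_names(),
    NGTDM = ngtdm_feature_names(),
    SFM = sfm_feature_names(),
    laws = laws_feature_names(),
    fractal = fractal_feature_names(),
    gabor = gabor_feature_names(),
    rfs = rfs_feature_names(),
    fourier = fourier_feature_names()
  )
  data.frame(name = unlist(fam, use.names = FALSE),
             family = rep(names(fam), lengths(fam)))
}

#' Extract the full 203-feature bank from one ROI
#'
#' Concatenates all twelve families in registry order. Deterministic, and
#' finite on any non-constant input. Family-level failures are re-raised with
#' the family name attached.
#'
#' @param roi a `roi_image`.
#' @param Ng grey levels for the quantized families (default 32).
#' @return Named numeric vector of length 203 with a `families` attribute.
#' @export
extract_all <- function(roi, Ng = 32) {
  stopifnot(inherits(roi, "roi_image"))
  # crop to the bounding box of valid pixels: features are then invariant to
  # padding the ROI with invalid pixels
  roi <- crop_to_valid(roi)
  q <- with_family("quantize", quantize(roi, Ng = Ng))
  vals <- c(
    with_family("histogram", histogram_features(roi)),
    with_family("GLCM", glcm_features(q)),
    with_family("GLRLM", glrlm_features(q)),
    with_family("GLSM", glsm_features(roi)),
    with_family("GLDS", glds_features(q)),
    with_family("NGTDM", ngtdm_features(q)),
    with_family("SFM", sfm_features(q)),
    with_family("laws", laws_features(roi)),
    with_family("fractal", fractal_features(roi)),
    with_family("transform", transform_features(roi))
  )
  reg <- feature_registry()
  stopifnot(identical(names(vals), reg$name))
  attr(vals, "families") <- reg$family
  vals
}

with_family <- function(family, expr) {
  tryCatch(expr, readiff_error = function(e) {
    stop_readiff(sprintf("[%s] %s", family, conditionMessage(e)),
                 class(e)[1])
  })
}

crop_to_valid <- function(roi) {
  if (all(roi$valid)) return(roi)
  idx <- which(roi$valid, arr.ind = TRUE)
  if (!nrow(idx)) stop_readiff("no valid pixels", "readiff_input_error")
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  if (rr[1] == 1 && cr[1] == 1 && rr[2] == nrow(roi$pixels) &&
      cr[2] == ncol(roi$pixels)) return(roi)
  out <- roi
  out$pixels <- roi$pixels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  out$valid <- roi$valid[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  out
}
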