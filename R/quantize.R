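#' Quantize an ROI to integer grey levels
#'
#' Equal-width binning of the valid pixel intensities between their minimum
#' and maximum into `Ng` levels `0..Ng-1`. Shared precursor of all
#' matrix-based texture families; equal-width binning between min and max
#' makes the levels invariant to affine intensity rescaling of the input.
#'
#' @param roi a `roi_image`.
#' @param Ng number of grey levels (default 32).
#' @return A `quantized_roi`: list with `levels` (integer matrix; invalid
#'   pixels hold 0 and must be ignored via `valid`), `valid` and `Ng`.
#' @export
quantize <- function(roi, Ng = 32) {
  stopifnot(inherits(roi, "roi_image"), Ng >= 2)
  v <- roi_values(roi)
  if (length(v) < 2) stop_readiff("too few valid pixels", "readiff_input_error")
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    stop_readiff("constant ROI: cannot quantize", "readiff_quantization_error")
  }
  lv <- floor((roi$pixels - rng[1]) / diff(rng) * Ng)
  lv[lv >= Ng] <- Ng - 1
  lv[lv < 0] <- 0
  lv[!roi$valid] <- 0L
  quantized_roi(matrix(as.integer(lv), nrow(lv), ncol(lv)), roi$valid, Ng)
}

quantized_roi <- function(levels, valid, Ng) {
  stopifnot(identical(dim(levels), dim(valid)))
  structure(list(levels = levels, valid = valid, Ng = as.integer(Ng)),
            class = "quantized_roi")
}
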