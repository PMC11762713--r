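#' Coarse breast segmentation
#'
#' Produces the breast-shape conditioning feature used by the
#' low-confidence refiner: global thresholding (Otsu by default, exploiting
#' the high breast/air contrast), hole filling, and selection of the
#' largest connected foreground component. The returned feature is the raw
#' binary mask itself, not a distance encoding.
#'
#' @param image Normalized matrix in `[0, 1]`.
#' @param threshold Either `"otsu"` (default) or a fixed numeric level.
#' @return Binary matrix with exactly one connected, hole-free foreground
#'   component.
#' @export
segment_breast <- function(image, threshold = "otsu") {
  stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 1)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    as.numeric(threshold)
  }
  fg <- image > thr
  if (!any(fg)) {
    stop(sprintf("no foreground above threshold %.4f", thr), call. = FALSE)
  }
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- (lab == which.max(sizes)) * 1
  filled <- EBImage::fillHull(keep)
  matrix(as.numeric(filled > 0), nrow(image), ncol(image))
}

# 8-connected component labeling (deterministic raster discovery order)
label_components <- function(mask) {
  .label_components8(matrix(as.logical(mask), nrow(mask), ncol(mask)))
}
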