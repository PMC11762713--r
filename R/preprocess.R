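#' Percentile intensity normalization
#'
#' Clips image intensities at the low and high percentiles of the
#' within-image distribution and maps the clipped range linearly to
#' `[0, 1]`. Values at or below the low percentile map to 0, values at or
#' above the high percentile map to 1. Percentiles follow the
#' linear-interpolation convention (`stats::quantile` type 7).
#'
#' @param image Numeric matrix.
#' @param lo_pct,hi_pct Percentile bounds (defaults 10 and 90).
#' @return Matrix with values in `[0, 1]`. A constant image (equal
#'   percentiles) returns all zeros with a warning.
#' @export
percentile_normalize <- function(image, lo_pct = 10, hi_pct = 90) {
  stopifnot(is.matrix(image), lo_pct < hi_pct)
  q <- quantile(image, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant image: percentiles coincide, returning all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  clamp01((image - q[1]) / (q[2] - q[1]))
}

#' Orient an image so the pectoral muscle sits upper-left
#'
#' Flips the image horizontally if the left half is dimmer than the right
#' half, and vertically if the top half is dimmer than the bottom half, so
#' that the bright pectoral wedge ends up in the upper-left corner. Any
#' masks passed alongside are flipped identically.
#'
#' @param image Numeric matrix.
#' @param ... Additional matrices (masks) to flip the same way.
#' @return If no masks are given, the oriented image; otherwise a list with
#'   `image` and the flipped masks (named as passed).
#' @export
orient_upper_left <- function(image, ...) {
  stopifnot(is.matrix(image), length(image) > 0)
  w <- ncol(image); h <- nrow(image)
  left <- mean(image[, seq_len(floor(w / 2))])
  right <- mean(image[, seq(w - floor(w / 2) + 1, w)])
  top <- mean(image[seq_len(floor(h / 2)), ])
  bottom <- mean(image[seq(h - floor(h / 2) + 1, h), ])
  fliph <- left < right
  flipv <- top < bottom
  fl <- function(m) {
    if (fliph) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (flipv) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m
  }
  masks <- list(...)
  if (!length(masks)) return(fl(image))
  c(list(image = fl(image)), lapply(masks, fl))
}

#' Resize an image or mask
#'
#' Bilinear interpolation for intensity images, nearest-neighbor for binary
#' masks (preserving binarity). Aspect distortion is permitted: the target
#' shape is applied unconditionally.
#'
#' @param image Numeric matrix.
#' @param target Length-2 integer vector `c(height, width)`; the default
#'   mirrors the working resolution used for full mammograms.
#' @param mask If `TRUE`, use nearest-neighbor interpolation.
#' @return Resized matrix.
#' @export
resize_image <- function(image, target = c(448, 320), mask = FALSE) {
  stopifnot(is.matrix(image), all(target >= 1))
  if (all(dim(image) == target)) return(image)
  out <- EBImage::resize(image, w = target[1], h = target[2],
                         filter = if (mask) "none" else "bilinear")
  out <- matrix(as.numeric(out), target[1], target[2])
  if (mask) out <- round(out)
  out
}

#' Intensity augmentation configuration
#'
#' Houses the random input perturbation used for both student and teacher
#' inputs during consistency training: random multiplicative contrast
#' adjustment about mid-gray and CLAHE (contrast-limited adaptive histogram
#' equalization). Both are intensity-only so that student and teacher
#' outputs stay pixel-aligned.
#'
#' @param contrast_range Multiplicative contrast factor interval.
#' @param p_contrast,p_clahe Per-transform application probabilities.
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tiles CLAHE tile grid (number of tiles per side).
#' @param seed Base seed; each augmentation draw is keyed by
#'   `(seed, draw)`.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(contrast_range = c(0.8, 1.2),
                           p_contrast = 0.5, p_clahe = 0.25,
                           clahe_clip = 2, clahe_tiles = 4, seed = 1L) {
  stopifnot(all(contrast_range > 0), p_contrast >= 0, p_contrast <= 1,
            p_clahe >= 0, p_clahe <= 1)
  structure(list(contrast_range = contrast_range, p_contrast = p_contrast,
                 p_clahe = p_clahe, clahe_clip = clahe_clip,
                 clahe_tiles = clahe_tiles, seed = as.integer(seed)),
            class = "augment_config")
}

#' Apply a random intensity augmentation
#'
#' Deterministic given `(config$seed, draw)`; geometric content is never
#' changed. Output is clipped to `[0, 1]`.
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param config An [augment_config()].
#' @param draw Integer keying this draw of the perturbation.
#' @return Perturbed matrix in `[0, 1]`.
#' @export
augment <- function(image, config, draw = 1L) {
  stopifnot(inherits(config, "augment_config"))
  with_local_seed(derive_seed(config$seed, draw), {
    if (runif(1) < config$p_contrast) {
      f <- runif(1, config$contrast_range[1], config$contrast_range[2])
      image <- (image - 0.5) * f + 0.5
    }
    if (runif(1) < config$p_clahe) {
      hw <- dim(image)
      image <- EBImage::clahe(clamp01(image), nx = config$clahe_tiles,
                              ny = config$clahe_tiles,
                              limit = config$clahe_clip)
      image <- matrix(as.numeric(image), hw[1], hw[2])
    }
    clamp01(image)
  })
}
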