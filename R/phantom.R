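#' Specify a synthetic phantom mammogram
#'
#' A phantom emulates a medio-lateral-oblique mammogram at desk scale: a
#' bright breast region against dark background, a brighter wedge-shaped
#' pectoral muscle in the upper-left corner, optional bright gland blobs, and
#' additive Gaussian noise. The pectoral boundary is a bowed chord from a
#' top-row intercept to a left-column intercept; its sharpness can be
#' degraded on selected rows to emulate a blurred or invisible boundary.
#'
#' @param height,width Frame size in pixels.
#' @param pectoral_intercepts Length-2 vector `c(top_col, left_row)`: the
#'   boundary meets the top row at column `top_col` and the left column at
#'   row `left_row`.
#' @param boundary_curvature Signed dimensionless bow of the boundary chord;
#'   positive bulges into the breast (convex wedge), negative is concave,
#'   zero is a straight chord. One sign per phantom.
#' @param blur_rows Integer vector of rows (or list of `c(from, to)`
#'   intervals) on which the boundary is degraded; ground-truth masks stay
#'   crisp.
#' @param blur_sigma Gaussian blur scale in pixels for blurred rows.
#' @param blur_fade Fraction of the pectoral-breast contrast retained in
#'   blurred rows before blurring. At the default, the faded step spread
#'   over the blur kernel leaves a per-pixel gradient comparable to the
#'   noise floor, emulating a clinically invisible boundary rather than a
#'   merely smoothed one.
#' @param pectoral_level,breast_level,background_level Intensities in
#'   `[0, 1]`, strictly ordered `background < breast < pectoral`.
#' @param gland_n Number of bright gland blobs added inside the breast
#'   (outside the pectoral region).
#' @param gland_radius Length-2 range of blob radii in pixels.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; generation is fully deterministic given it.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(height = 64, width = 64,
                         pectoral_intercepts = c(round(width * 0.55),
                                                 round(height * 0.8)),
                         boundary_curvature = 0,
                         blur_rows = integer(0),
                         blur_sigma = 3,
                         blur_fade = 0.25,
                         pectoral_level = 0.85,
                         breast_level = 0.55,
                         background_level = 0.05,
                         gland_n = 0,
                         gland_radius = c(3, 6),
                         noise_sigma = 0.02,
                         seed = 1L) {
  blur_rows <- normalize_rows(blur_rows)
  spec <- structure(
    list(height = as.integer(height), width = as.integer(width),
         pectoral_intercepts = as.numeric(pectoral_intercepts),
         boundary_curvature = as.numeric(boundary_curvature),
         blur_rows = blur_rows, blur_sigma = as.numeric(blur_sigma),
         blur_fade = as.numeric(blur_fade),
         pectoral_level = pectoral_level, breast_level = breast_level,
         background_level = background_level,
         gland_n = as.integer(gland_n), gland_radius = as.numeric(gland_radius),
         noise_sigma = as.numeric(noise_sigma), seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
}

normalize_rows <- function(blur_rows) {
  if (is.list(blur_rows)) {
    blur_rows <- unlist(lapply(blur_rows, function(iv) seq(iv[1], iv[2])))
  }
  sort(unique(as.integer(blur_rows)))
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$height >= 8, spec$width >= 8)
  ct <- spec$pectoral_intercepts[1]
  rl <- spec$pectoral_intercepts[2]
  if (is.na(ct) || is.na(rl) || ct < 2 || ct > spec$width - 1 ||
      rl < 2 || rl > spec$height - 1) {
    stop("degenerate wedge: pectoral_intercepts (", ct, ", ", rl,
         ") fall outside the frame interior", call. = FALSE)
  }
  if (length(spec$blur_rows) &&
      (min(spec$blur_rows) < 1 || max(spec$blur_rows) > spec$height)) {
    stop("blur_rows must lie within [1, height]", call. = FALSE)
  }
  lv <- c(spec$background_level, spec$breast_level, spec$pectoral_level)
  if (any(lv < 0) || any(lv > 1) || any(diff(lv) <= 0)) {
    stop("intensity levels must satisfy 0 <= background < breast <= pectoral <= 1",
         call. = FALSE)
  }
  if (spec$noise_sigma < 0 || spec$blur_sigma <= 0) {
    stop("noise_sigma must be >= 0 and blur_sigma > 0", call. = FALSE)
  }
  if (spec$blur_fade < 0 || spec$blur_fade > 1) {
    stop("blur_fade must lie in [0, 1]", call. = FALSE)
  }
  spec
}

# boundary column (fractional) per row; NA beyond the wedge
phantom_boundary_col <- function(spec) {
  rl <- spec$pectoral_intercepts[2]
  ct <- spec$pectoral_intercepts[1]
  r <- seq_len(spec$height)
  t <- (r - 1) / (rl - 1)
  col <- ct + (1 - ct) * t + spec$boundary_curvature * ct / 2 * sin(pi * t)
  col[r > rl] <- NA_real_
  pmin(pmax(col, 1), spec$width - 0.5)
}

#' Generate a phantom mammogram with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: pectoral and breast
#' masks (always crisp), the image with row-selective boundary blur, gland
#' blobs and noise, and a per-row boundary-clarity record.
#'
#' Each row of the pectoral mask is a contiguous run starting at column 1,
#' so the pectoral boundary crosses every row at most once -- the property
#' the row-based confidence model relies on.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: a list with elements `image`
#'   (matrix in `[0, 1]`), `pectoral_mask`, `breast_mask` (binary matrices),
#'   `clarity` (per-row `"sharp"`/`"blurred"`), `boundary_col` (fractional
#'   boundary column per row, `NA` beyond the wedge) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7, blur_rows = 10:20))
#' table(ph$clarity)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width

  bcol <- phantom_boundary_col(spec)
  pect <- matrix(0, h, w)
  for (r in seq_len(h)) {
    if (!is.na(bcol[r])) pect[r, seq_len(max(1L, floor(bcol[r])))] <- 1
  }

  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ellipse <- ((cc - 1) / (0.92 * w))^2 +
    ((rr - 0.3 * h) / (0.95 * h))^2 <= 1
  breast <- (ellipse | pect == 1) * 1

  img <- matrix(spec$background_level, h, w)
  img[breast == 1] <- spec$breast_level
  img[pect == 1] <- spec$pectoral_level

  with_local_seed(spec$seed, {
    if (spec$gland_n > 0) {
      ok <- which(breast == 1 & pect == 0)
      amp <- 0.8 * (spec$pectoral_level - spec$breast_level)
      for (i in seq_len(spec$gland_n)) {
        ctr <- ok[sample.int(length(ok), 1)]
        cr <- ((ctr - 1) %% h) + 1
        ccol <- ((ctr - 1) %/% h) + 1
        rad <- runif(1, spec$gland_radius[1], spec$gland_radius[2])
        bump <- amp * exp(-((rr - cr)^2 + (cc - ccol)^2) / (2 * (rad / 2)^2))
        img <- img + bump * (breast == 1 & pect == 0)
      }
    }
    if (length(spec$blur_rows)) {
      # fade the pectoral step toward the breast level, then blur: blurred
      # rows lose the boundary evidence itself, not just its sharpness
      flat <- img
      flat[pect == 1] <- spec$breast_level +
        spec$blur_fade * (img[pect == 1] - spec$breast_level)
      blurred <- safe_gblur(flat, spec$blur_sigma)
      img[spec$blur_rows, ] <- blurred[spec$blur_rows, ]
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w)
    }
  })

  clarity <- rep("sharp", h)
  clarity[spec$blur_rows] <- "blurred"

  structure(list(image = clamp01(img), pectoral_mask = pect,
                 breast_mask = breast, clarity = clarity,
                 boundary_col = bcol, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d, %d blurred rows, seed %d>\n",
              x$spec$height, x$spec$width,
              sum(x$clarity == "blurred"), x$spec$seed))
  invisible(x)
}

#' Random phantom-spec sampler
#'
#' Returns a sampler closure `function(seed, split)` producing randomized
#' [phantom_spec()]s, used by [generate_dataset()]. The fraction of blurred
#' boundary rows is drawn from `blur_frac` for the labeled/test default and
#' from `blur_frac_unlabeled` for the unlabeled split, emulating the domain
#' shift of a second data center whose boundaries are systematically less
#' visible.
#'
#' @param height,width Frame size of sampled phantoms.
#' @param blur_frac Range of the blurred-row fraction for labeled/test
#'   phantoms.
#' @param blur_frac_unlabeled Range for unlabeled phantoms (more blur).
#' @param gland_n Number of gland blobs per phantom.
#' @param noise_sigma Additive noise level.
#' @return A function `(seed, split = "labeled")` returning a `phantom_spec`.
#' @export
phantom_sampler <- function(height = 64, width = 64,
                            blur_frac = c(0, 0.2),
                            blur_frac_unlabeled = c(0.4, 0.7),
                            gland_n = 2, noise_sigma = 0.02) {
  function(seed, split = "labeled") {
    with_local_seed(seed, {
      rng <- if (identical(split, "unlabeled")) blur_frac_unlabeled else blur_frac
      ct <- round(runif(1, 0.4, 0.7) * width)
      rl <- round(runif(1, 0.6, 0.9) * height)
      curv <- runif(1, -0.35, 0.35)
      frac <- runif(1, rng[1], rng[2])
      nblur <- round(frac * rl)
      blur <- integer(0)
      if (nblur > 0) {
        start <- sample.int(max(1L, rl - nblur + 1L), 1)
        blur <- seq(start, length.out = nblur)
      }
      phantom_spec(height = height, width = width,
                   pectoral_intercepts = c(ct, rl),
                   boundary_curvature = curv,
                   blur_rows = blur, blur_sigma = 3,
                   gland_n = gland_n, noise_sigma = noise_sigma,
                   seed = sample.int(.Machine$integer.max, 1))
    })
  }
}

#' Generate labeled/unlabeled/test phantom splits
#'
#' Draws disjoint seed streams for the three splits. The unlabeled split is
#' sampled with `split = "unlabeled"`, which the default [phantom_sampler()]
#' maps to systematically more boundary blur.
#'
#' @param n_labeled,n_unlabeled,n_test Split sizes (each `>= 0`).
#' @param spec_sampler Sampler closure, see [phantom_sampler()].
#' @param seed Integer seed for the whole bundle.
#' @param blur_test If `TRUE`, the test split is drawn like the unlabeled
#'   split (blurred); otherwise like the labeled split.
#' @return A list of class `phantom_dataset` with elements `labeled`,
#'   `unlabeled`, `test` (lists of [generate_phantom()] results) and `seed`.
#' @export
generate_dataset <- function(n_labeled, n_unlabeled, n_test,
                             spec_sampler = phantom_sampler(),
                             seed = 1L, blur_test = TRUE) {
  stopifnot(n_labeled >= 0, n_unlabeled >= 0, n_test >= 0)
  gen <- function(n, split, offset) {
    lapply(seq_len(n), function(i) {
      generate_phantom(spec_sampler(derive_seed(seed, offset + i), split))
    })
  }
  structure(list(
    labeled = gen(n_labeled, "labeled", 0L),
    unlabeled = gen(n_unlabeled, "unlabeled", 100000L),
    test = gen(n_test, if (blur_test) "unlabeled" else "labeled", 200000L),
    seed = as.integer(seed)), class = "phantom_dataset")
}

#' Randomly erase whole rows of a binary mask
#'
#' Zeroes a contiguous block of the mask's nonempty rows covering
#' approximately `fraction` of them. Used to emulate partially-confident
#' annotations when training the low-confidence refiner: the surviving rows
#' play the role of high-confidence predictions and the erased rows must be
#' reconstructed from the shape prior.
#'
#' @param mask Binary matrix.
#' @param fraction Fraction of nonempty rows to erase, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `mask` (erased copy) and `kept_rows` (logical
#'   per-row indicator, `TRUE` where the row survived).
#' @export
erase_rows <- function(mask, fraction, seed = 1L) {
  stopifnot(is.matrix(mask), is_binary(mask),
            fraction >= 0, fraction <= 1)
  kept <- rep(TRUE, nrow(mask))
  nonempty <- which(rowSums(mask) > 0)
  if (!length(nonempty) || fraction == 0) {
    return(list(mask = mask, kept_rows = kept))
  }
  k <- round(fraction * length(nonempty))
  if (k > 0) {
    start <- with_local_seed(seed,
      sample.int(length(nonempty) - k + 1L, 1))
    rows <- nonempty[seq(start, length.out = k)]
    mask[rows, ] <- 0
    kept[rows] <- FALSE
  }
  list(mask = mask, kept_rows = kept)
}

#' Write a phantom dataset to disk
#'
#' Writes each phantom's image and masks as PNG files plus a plain-text
#' manifest table (`manifest.tsv`: path, split, index, blurred-row count).
#'
#' @param dataset A [generate_dataset()] bundle.
#' @param dir Output directory (created if missing).
#' @return The manifest as a tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("labeled", "unlabeled", "test")) {
    for (i in seq_along(dataset[[split]])) {
      ph <- dataset[[split]][[i]]
      base <- sprintf("%s_%03d", split, i)
      EBImage::writeImage(t(ph$image), file.path(dir, paste0(base, ".png")),
                          bits.per.sample = 16)
      EBImage::writeImage(t(ph$pectoral_mask),
                          file.path(dir, paste0(base, "_pectoral.png")))
      EBImage::writeImage(t(ph$breast_mask),
                          file.path(dir, paste0(base, "_breast.png")))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = paste0(base, ".png"), split = split, index = i,
        blurred_rows = sum(ph$clarity == "blurred"))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
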