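#' Snapshot-ensemble predictions container
#'
#' Bundles `K >= 2` per-pixel foreground-probability maps produced by
#' models saved at different training epochs (a snapshot ensemble), the
#' input to uncertainty estimation.
#'
#' @param probs List of matrices, or a 3-D array `(H, W, K)`, each grid in
#'   `[0, 1]`.
#' @return An object of class `ensemble_predictions` (array `(H, W, K)`).
#' @export
ensemble_predictions <- function(probs) {
  if (is.list(probs)) {
    probs <- array(unlist(probs), dim = c(dim(probs[[1]]), length(probs)))
  }
  stopifnot(length(dim(probs)) == 3)
  if (dim(probs)[3] < 2) {
    stop("a snapshot ensemble needs K >= 2 prediction maps", call. = FALSE)
  }
  if (min(probs) < 0 || max(probs) > 1) {
    stop("ensemble probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(probs, class = "ensemble_predictions")
}

#' Pixelwise predictive entropy of a snapshot ensemble
#'
#' Forms the ensemble-mean foreground probability per pixel and returns its
#' binary Shannon entropy (natural log), `-p*log(p) - (1-p)*log(1-p)` with
#' `0 log 0 := 0`. Values lie in `[0, log 2]`; high entropy marks model
#' disagreement and hence low confidence.
#'
#' @param ens An [ensemble_predictions()] object (or 3-D array, `K >= 2`).
#' @return Matrix of entropies.
#' @export
pixel_entropy <- function(ens) {
  if (!inherits(ens, "ensemble_predictions")) ens <- ensemble_predictions(ens)
  p <- rowMeans(unclass(ens), dims = 2)
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  -xlogx(p) - xlogx(1 - p)
}

#' White top-hat filtering
#'
#' Subtracts the grayscale morphological opening (flat horizontal line
#' structuring element of width `se_width`) from the input. Structures
#' narrower than the element keep a high residual; wider structures are
#' suppressed. The quasi-vertical pectoral boundary produces a thin
#' high-entropy band when clear and a wide one when blurred, so a
#' horizontal element measures exactly the width that distinguishes them.
#'
#' Windows are clipped at the image border (the erosion minimum and
#' dilation maximum run over the pixels that exist), so a constant map has
#' an exactly zero residual everywhere including the border.
#'
#' @param map Nonnegative matrix.
#' @param se_width Structuring-element width in pixels (`>= 1`).
#' @return Nonnegative residual matrix.
#' @export
top_hat <- function(map, se_width = 7) {
  stopifnot(is.matrix(map), se_width >= 1)
  p_left <- (se_width - 1) %/% 2
  p_right <- se_width - 1 - p_left
  eroded <- row_morph(map, -p_left, p_right, pmin, Inf)
  opened <- row_morph(eroded, -p_right, p_left, pmax, -Inf)  # reflected SE
  pmax(map - opened, 0)
}

# running min/max along rows over column offsets [lo, hi], border-clipped
row_morph <- function(m, lo, hi, reduce, pad) {
  w <- ncol(m)
  out <- matrix(pad, nrow(m), w)
  for (off in lo:hi) {
    src <- seq_len(w) + off
    ok <- src >= 1 & src <= w
    out[, ok] <- reduce(out[, ok, drop = FALSE], m[, src[ok], drop = FALSE])
  }
  out
}

#' Coherence-enhancing shock filtering
#'
#' Iterative morphological sharpening along the dominant local orientation:
#' each iteration smooths the map at scale `sigma`, estimates the dominant
#' eigenvector `w` of the structure tensor smoothed at scale `rho`, and
#' applies an upwind dilation (where the second directional derivative
#' `v_ww < 0`) or erosion (`v_ww > 0`) of magnitude `dt * |grad|`. Used to
#' consolidate the thin boundary response before thresholding; output range
#' stays within the input range.
#'
#' @param map Numeric matrix.
#' @param sigma Pre-smoothing scale (pixels).
#' @param rho Structure-tensor integration scale (pixels).
#' @param dt Time step per iteration.
#' @param n_iter Number of iterations.
#' @return Filtered matrix.
#' @export
cesf <- function(map, sigma = 1.5, rho = 4, dt = 0.25, n_iter = 10) {
  stopifnot(is.matrix(map), sigma > 0, rho > 0, dt > 0, n_iter >= 0)
  lo <- min(map); hi <- max(map)
  if (hi - lo == 0) return(map)
  for (it in seq_len(n_iter)) {
    u <- safe_gblur(map, sigma)
    gx <- cdiff_col(u); gy <- cdiff_row(u)
    j11 <- safe_gblur(gx * gx, rho)
    j12 <- safe_gblur(gx * gy, rho)
    j22 <- safe_gblur(gy * gy, rho)
    phi <- 0.5 * atan2(2 * j12, j11 - j22)  # dominant orientation
    wx <- cos(phi); wy <- sin(phi)
    uxx <- cdiff_col(gx); uyy <- cdiff_row(gy); uxy <- cdiff_row(gx)
    vww <- wx^2 * uxx + 2 * wx * wy * uxy + wy^2 * uyy
    dpx <- fdiff_col(map); dmx <- bdiff_col(map)
    dpy <- fdiff_row(map); dmy <- bdiff_row(map)
    grad_dil <- sqrt(pmax(dmx, 0)^2 + pmin(dpx, 0)^2 +
                     pmax(dmy, 0)^2 + pmin(dpy, 0)^2)
    grad_ero <- sqrt(pmin(dmx, 0)^2 + pmax(dpx, 0)^2 +
                     pmin(dmy, 0)^2 + pmax(dpy, 0)^2)
    s <- -sign(vww)
    map <- map + dt * ifelse(s > 0, grad_dil, ifelse(s < 0, -grad_ero, 0))
    map <- pmin(pmax(map, lo), hi)
  }
  map
}

# finite differences with replicated borders (columns = x, rows = y)
cdiff_col <- function(m) (shift_col(m, -1) - shift_col(m, 1)) / 2
cdiff_row <- function(m) (shift_row(m, -1) - shift_row(m, 1)) / 2
fdiff_col <- function(m) shift_col(m, -1) - m
bdiff_col <- function(m) m - shift_col(m, 1)
fdiff_row <- function(m) shift_row(m, -1) - m
bdiff_row <- function(m) m - shift_row(m, 1)

shift_col <- function(m, by) {
  w <- ncol(m)
  idx <- pmin(pmax(seq_len(w) - by, 1), w)
  m[, idx, drop = FALSE]
}
shift_row <- function(m, by) {
  h <- nrow(m)
  idx <- pmin(pmax(seq_len(h) - by, 1), h)
  m[idx, , drop = FALSE]
}

#' Select the boundary as the largest connected component
#'
#' Binarizes the map at `threshold` and keeps only the largest 8-connected
#' foreground component, discarding speckle and gland-like distractors. An
#' empty mask is returned if nothing survives the threshold.
#'
#' @param map Numeric matrix.
#' @param threshold Absolute binarization level (`>= 0`).
#' @return Binary matrix.
#' @export
select_boundary <- function(map, threshold) {
  stopifnot(is.matrix(map), threshold >= 0)
  bin <- map >= threshold
  if (!any(bin)) return(matrix(0, nrow(map), ncol(map)))
  lab <- label_components(bin)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

#' Row-based confidence partition
#'
#' Assigns per-row uncertainty `Pi[r] = 0` if row `r` intersects the
#' selected boundary mask and `1` otherwise, then partitions rows into
#' high-confidence (`beta_h = 1(Pi < delta)`) and low-confidence
#' (`beta_l = 1(Pi >= delta)`) sets. Rows crossed by a clearly visible
#' boundary are exactly the rows where the teacher prediction can be
#' trusted. With `continuous = TRUE`, `Pi[r]` is instead the fraction of
#' the row covered by the thresholded response (an experimental variant).
#'
#' @param boundary Binary boundary mask (from [select_boundary()]).
#' @param delta Threshold on row uncertainty, in `(0, 1)`.
#' @param continuous Use the continuous row-uncertainty variant.
#' @return An object of class `confidence_partition`: list with
#'   `row_uncertainty`, `delta`, `beta_h`, `beta_l` (0/1 vectors) and their
#'   pixel-grid broadcasts `beta_h_mask`, `beta_l_mask`.
#' @export
row_confidence <- function(boundary, delta = 0.5, continuous = FALSE) {
  stopifnot(is.matrix(boundary), delta > 0, delta < 1)
  hits <- rowSums(boundary > 0)
  pi_row <- if (continuous) {
    1 - hits / ncol(boundary)
  } else {
    as.numeric(hits == 0)
  }
  beta_h <- as.numeric(pi_row < delta)
  beta_l <- 1 - beta_h
  structure(list(
    row_uncertainty = pi_row, delta = delta,
    beta_h = beta_h, beta_l = beta_l,
    beta_h_mask = row_broadcast(beta_h, ncol(boundary)),
    beta_l_mask = row_broadcast(beta_l, ncol(boundary))),
    class = "confidence_partition")
}

#' @export
print.confidence_partition <- function(x, ...) {
  cat(sprintf("<confidence_partition: %d/%d rows high-confidence, delta=%g>\n",
              sum(x$beta_h), length(x$beta_h), x$delta))
  invisible(x)
}

#' Tidy a confidence partition into a per-row table
#'
#' @param x A `confidence_partition`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `uncertainty`, `beta_h`, `beta_l`.
#' @export
tidy.confidence_partition <- function(x, ...) {
  tibble::tibble(row = seq_along(x$beta_h),
                 uncertainty = x$row_uncertainty,
                 beta_h = x$beta_h, beta_l = x$beta_l)
}

#' Restrict a prediction to high-confidence rows
#'
#' Elementwise product of the teacher prediction with the broadcast
#' high-confidence row indicator.
#'
#' @param yu Probability matrix (teacher prediction).
#' @param part A [row_confidence()] partition.
#' @return Matrix equal to `yu` on high-confidence rows, zero elsewhere.
#' @export
high_confidence_prediction <- function(yu, part) {
  assert_same_shape(yu, part$beta_h_mask, "prediction and partition")
  yu * part$beta_h_mask
}

#' Full uncertainty-estimation pipeline
#'
#' Composition of [pixel_entropy()], [top_hat()], [cesf()],
#' [select_boundary()] and [row_confidence()], retaining every intermediate
#' map for inspection and plotting.
#'
#' The entropy is computed over the *votes* of the snapshot ensemble: each
#' snapshot's probability map is binarized at 0.5 before averaging, so the
#' entropy measures disagreement about the predicted label rather than
#' each model's output softness. A consistency-trained teacher keeps broad
#' mid-range probabilities whose softness would otherwise flood the map
#' with high entropy everywhere, masking the agreement structure the row
#' decision is built on.
#'
#' Several numerical-conditioning steps make the row decision robust at
#' desk scale:
#'
#' * the vote-entropy map is lightly pre-smoothed (`pre_sigma`), linking
#'   the discrete disagreement pixels of a clear boundary into a
#'   contiguous thin ridge;
#' * before the top-hat the response is saturated (clipped) at
#'   `saturation * log 2`, turning the high-response zone into a plateau
#'   whose *width* the top-hat measures -- on a peaked profile the top-hat
#'   would measure peak curvature instead, which does not separate clear
#'   from blurred boundaries;
#' * before component selection, two row-level gates clear rows that
#'   cannot carry a clear boundary: rows whose disagreement width (vote
#'   entropy above `0.5 * log 2`) exceeds `max_width`, and rows whose
#'   majority vote contains no foreground at all -- with no predicted
#'   muscle there is no predicted boundary to trust, and an ensemble
#'   confidently predicting "nothing" across an invisible boundary would
#'   otherwise be promoted to high confidence;
#' * rows with *zero* disagreement and a nonempty majority vote are
#'   accepted as high-confidence directly (their predicted boundary pixel
#'   joins the boundary mask): agreement-based uncertainty has nothing to
#'   distrust there, and an ensemble of identical predictions must reduce
#'   to plain mean-teacher behavior.
#'
#' All thresholds sit on the absolute entropy scale (`log 2` is the
#' attainable maximum), so an ensemble with no thin disagreement ridge
#' and no agreed foreground anywhere selects no boundary at all.
#'
#' @param ens An [ensemble_predictions()] object.
#' @param se_width Top-hat structuring-element width (pixels).
#' @param sigma,rho,dt,n_iter Shock-filter parameters, see [cesf()].
#' @param pre_sigma Gaussian pre-smoothing scale for the vote-entropy map
#'   (pixels; 0 disables).
#' @param saturation Clip level for the entropy response, as a fraction of
#'   `log 2`.
#' @param threshold_frac Binarization threshold, as a fraction of the
#'   saturation level.
#' @param max_width Maximum disagreement width (pixels) for a row to
#'   count as crossed by a clear boundary.
#' @param delta Row-uncertainty threshold, see [row_confidence()].
#' @param continuous Use the continuous row-uncertainty variant.
#' @return An object of class `uncertainty_estimate`: list with
#'   `pi_pixel` (vote entropy), `tophat`, `cesf`, `row_width`
#'   (disagreement width per row), `boundary`, `partition`.
#' @export
estimate_confidence <- function(ens, se_width = 7, sigma = 1.5, rho = 4,
                                dt = 0.25, n_iter = 10, pre_sigma = 0.8,
                                saturation = 0.45, threshold_frac = 0.5,
                                max_width = 5, delta = 0.5,
                                continuous = FALSE) {
  if (!inherits(ens, "ensemble_predictions")) ens <- ensemble_predictions(ens)
  votes <- (unclass(ens) >= 0.5) * 1
  pi_pixel <- pixel_entropy(ensemble_predictions(votes))
  pv <- rowMeans(votes, dims = 2)
  smoothed <- if (pre_sigma > 0) safe_gblur(pi_pixel, pre_sigma) else pi_pixel
  sat <- saturation * log(2)
  th <- top_hat(pmin(smoothed, sat), se_width = se_width)
  sh <- cesf(th, sigma = sigma, rho = rho, dt = dt, n_iter = n_iter)
  row_width <- rowSums(pi_pixel > 0.5 * log(2))
  fg_rows <- rowSums(pv >= 0.5) > 0
  sh_gated <- sh
  sh_gated[row_width > max_width | !fg_rows, ] <- 0
  boundary <- select_boundary(sh_gated, threshold = threshold_frac * sat)
  agreed <- which(row_width == 0 & fg_rows)
  for (r in agreed) {
    boundary[r, max(which(pv[r, ] >= 0.5))] <- 1
  }
  part <- row_confidence(boundary, delta = delta, continuous = continuous)
  structure(list(pi_pixel = pi_pixel, tophat = th, cesf = sh,
                 row_width = row_width, boundary = boundary,
                 partition = part),
            class = "uncertainty_estimate")
}

#' @export
print.uncertainty_estimate <- function(x, ...) {
  print(x$partition)
  invisible(x)
}

#' Does row confidence discriminate blurred from sharp boundary rows?
#'
#' For each phantom, predicts with the snapshot ensemble of a trained
#' model, runs [estimate_confidence()], and compares the fraction of
#' blurred boundary rows assigned low confidence with the same fraction
#' over sharp boundary rows. Rows beyond the pectoral wedge carry no
#' boundary and are excluded from both groups.
#'
#' @param state A trained `train_state` whose ring holds `>= 2` snapshots.
#' @param phantoms List of [generate_phantom()] results.
#' @param uncertainty List of [estimate_confidence()] arguments.
#' @return A tibble with one row per phantom: `frac_low_blurred`,
#'   `frac_low_sharp`, and `discriminates` (whether blurred > sharp).
#' @export
uncertainty_discrimination <- function(state, phantoms,
                                       uncertainty = list()) {
  dplyr::bind_rows(purrr::map(seq_along(phantoms), function(i) {
    ph <- phantoms[[i]]
    ens <- snapshot_predict(state, ph$image)
    est <- do.call(estimate_confidence, c(list(ens), uncertainty))
    wedge <- !is.na(ph$boundary_col)
    blur <- wedge & ph$clarity == "blurred"
    sharp <- wedge & ph$clarity == "sharp"
    fb <- mean(est$partition$beta_l[blur])
    fs <- mean(est$partition$beta_l[sharp])
    tibble::tibble(phantom = i, frac_low_blurred = fb,
                   frac_low_sharp = fs, discriminates = fb > fs)
  }))
}
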