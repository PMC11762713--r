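#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` over foreground pixels. Two empty masks score
#' 1 (a perfect background-only prediction is not penalized).
#'
#' @param a,b Binary matrices of one shape.
#' @return Score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_mask_pair(a, b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a * b) / (na + nb)
}

#' Intersection over union (Jaccard index)
#'
#' `TP / (TP + FP + FN)`. Two empty masks score 1.
#'
#' @param a,b Binary matrices of one shape.
#' @return Score in `[0, 1]`.
#' @export
iou <- function(a, b) {
  check_mask_pair(a, b)
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

check_mask_pair <- function(a, b) {
  assert_same_shape(a, b, "masks")
  if (!is_binary(a) || !is_binary(b)) {
    stop("masks must be binary (0/1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Hausdorff distance between two masks
#'
#' The exact symmetric Hausdorff distance between the foreground pixel
#' coordinate sets (pixel centers, Euclidean): the larger of the two
#' directed maxima of nearest-point distances. Computed via exact
#' Euclidean distance transforms.
#'
#' @param a,b Binary matrices, both nonempty.
#' @return Distance in pixels.
#' @export
hausdorff <- function(a, b) {
  check_mask_pair(a, b)
  if (sum(a) == 0 || sum(b) == 0) {
    stop("hausdorff distance is undefined for an empty mask", call. = FALSE)
  }
  h_ab <- max(dist_to_mask(b)[a == 1])
  h_ba <- max(dist_to_mask(a)[b == 1])
  max(h_ab, h_ba)
}

# per-pixel exact Euclidean distance to the nearest foreground pixel of m
dist_to_mask <- function(m) {
  d <- EBImage::distmap(1 - m, metric = "euclidean")
  matrix(as.numeric(d), nrow(m), ncol(m))
}

#' Overall unacceptable segmentation ratio
#'
#' Counts segmentations whose Dice score (in percent) falls strictly below
#' `threshold` and reports the count and its ratio to the total. The
#' companion clinical-review criterion of the full definition is outside
#' computational scope; only the Dice criterion is implemented.
#'
#' @param dice_scores Numeric vector of Dice scores in percent (`[0, 100]`).
#' @param threshold Acceptability threshold in percent (default 85).
#' @return A list with `count` and `ratio`.
#' @export
ousr <- function(dice_scores, threshold = 85) {
  if (!length(dice_scores)) {
    stop("ousr needs at least one score", call. = FALSE)
  }
  stopifnot(all(dice_scores >= 0), all(dice_scores <= 100))
  n <- sum(dice_scores < threshold)
  list(count = n, ratio = n / length(dice_scores))
}

#' Evaluate predicted masks against ground truth
#'
#' @param pred List of binary prediction masks.
#' @param truth List of matching ground-truth masks.
#' @return A tibble with one row per pair (`dice`, `iou`, `hausdorff`;
#'   `hausdorff` is `NA` when either mask is empty) plus an `image` index.
#' @export
evaluate_masks <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  dplyr::bind_rows(purrr::map(seq_along(pred), function(i) {
    hd <- if (sum(pred[[i]]) > 0 && sum(truth[[i]]) > 0) {
      hausdorff(pred[[i]], truth[[i]])
    } else {
      NA_real_
    }
    tibble::tibble(image = i, dice = dice(pred[[i]], truth[[i]]),
                   iou = iou(pred[[i]], truth[[i]]), hausdorff = hd)
  }))
}

#' Summarize an evaluation table
#'
#' @param eval_tbl Output of [evaluate_masks()].
#' @param ousr_threshold OUSR threshold in percent.
#' @return One-row tibble: mean Dice, mean IoU, mean Hausdorff distance,
#'   OUSR count and ratio.
#' @export
summarize_evaluation <- function(eval_tbl, ousr_threshold = 85) {
  ou <- ousr(100 * eval_tbl$dice, threshold = ousr_threshold)
  tibble::tibble(mean_dice = mean(eval_tbl$dice),
                 mean_iou = mean(eval_tbl$iou),
                 mean_hausdorff = mean(eval_tbl$hausdorff, na.rm = TRUE),
                 ousr_count = ou$count, ousr_ratio = ou$ratio,
                 n = nrow(eval_tbl))
}
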