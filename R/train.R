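#' Training configuration for the segmentation regimes
#'
#' @param epochs Training epochs.
#' @param lr Adam learning rate for the student.
#' @param base,levels Student/teacher U-Net capacity (see [unet_init()]).
#' @param ema_decay Teacher exponential-moving-average decay per step.
#' @param consistency_weight Weight of the consistency loss (1 reproduces
#'   the unweighted sum of the printed objective).
#' @param ramp_up If `> 0`, the consistency weight is multiplied by a
#'   sigmoid ramp `exp(-5 (1 - t/ramp_up)^2)` for the first `ramp_up`
#'   epochs (off by default).
#' @param cadence Epoch interval between teacher snapshots once the
#'   validation loss has stabilized.
#' @param ring_k Snapshot ring capacity (ensemble size K).
#' @param stabilize_tol Relative improvement of the validation loss below
#'   which it counts as stabilized (snapshotting then starts).
#' @param aug An [augment_config()] for the input perturbation.
#' @param uncertainty List of [estimate_confidence()] arguments.
#' @param refiner Trained [refiner_bundle()] (required for the `ours`
#'   regime unless `force_high_confidence`).
#' @param force_high_confidence Debug/ablation flag: treat every row as
#'   high-confidence, making `ours` reproduce mean-teacher step for step.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20, lr = 2e-3, base = 8, levels = 3,
                         ema_decay = 0.99, consistency_weight = 1,
                         ramp_up = 0, cadence = 5, ring_k = 4,
                         stabilize_tol = 0.01,
                         aug = augment_config(),
                         uncertainty = list(),
                         refiner = NULL,
                         force_high_confidence = FALSE) {
  structure(list(epochs = epochs, lr = lr, base = base, levels = levels,
                 ema_decay = ema_decay,
                 consistency_weight = consistency_weight,
                 ramp_up = ramp_up, cadence = cadence, ring_k = ring_k,
                 stabilize_tol = stabilize_tol, aug = aug,
                 uncertainty = uncertainty, refiner = refiner,
                 force_high_confidence = force_high_confidence),
            class = "train_config")
}

new_train_state <- function(config, seed) {
  student <- unet_init(in_ch = 1, base = config$base, levels = config$levels,
                       seed = derive_seed(seed, 11L))
  teacher <- student
  structure(list(student = student, teacher = teacher,
                 ema_decay = config$ema_decay,
                 ring = list(), cadence = config$cadence,
                 ring_k = config$ring_k, epoch = 0L,
                 stabilized_epoch = NA_integer_,
                 best_par = student$par, best_val = Inf,
                 best_teacher_par = teacher$par, best_teacher_val = Inf,
                 opt = adam_init(student$par),
                 history = tibble::tibble(),
                 seed = as.integer(seed)),
            class = "train_state")
}

#' Update the teacher by exponential moving average
#'
#' Every teacher parameter moves toward the student:
#' `theta' <- decay * theta' + (1 - decay) * theta`.
#'
#' @param state A `train_state` (from [train_segmenter()] internals).
#' @return The state with an updated teacher.
#' @export
ema_update <- function(state) {
  stopifnot(inherits(state, "train_state"))
  d <- state$ema_decay
  state$teacher$par <- tree_map2(state$teacher$par, state$student$par,
                                 function(tp, sp) d * tp + (1 - d) * sp)
  state
}

#' Supervised segmentation loss
#'
#' Pixel-mean squared error between the student's prediction on the
#' (optionally augmented) image and the binary label.
#'
#' @param model A [unet_init()] network.
#' @param image Input matrix in `[0, 1]`.
#' @param label Binary matrix.
#' @param aug Optional [augment_config()]; `NULL` disables perturbation.
#' @param draw Integer keying the augmentation draw.
#' @return Scalar loss.
#' @export
supervised_loss <- function(model, image, label, aug = NULL, draw = 1L) {
  stopifnot(is_binary(label))
  assert_same_shape(image, label, "image and label")
  x <- if (is.null(aug)) image else augment(image, aug, draw)
  y <- unet_forward(model, x)$y
  mean((y - label)^2)
}

#' Teacher prediction
#'
#' Teacher forward pass on a perturbed input; no gradient flows to the
#' teacher (its weights are EMA copies, never optimized directly).
#'
#' @param state A `train_state`.
#' @param image Input matrix.
#' @param aug Optional [augment_config()].
#' @param draw Integer keying the perturbation draw.
#' @return Probability matrix.
#' @export
teacher_predict <- function(state, image, aug = NULL, draw = 1L) {
  x <- if (is.null(aug)) image else augment(image, aug, draw)
  unet_forward(state$teacher, x)$y
}

#' Predictions of the snapshot ensemble
#'
#' One unperturbed forward pass per snapshot in the ring, stacked into an
#' [ensemble_predictions()] object.
#'
#' @param state A `train_state` whose ring holds `K >= 2` snapshots.
#' @param image Input matrix.
#' @return An `ensemble_predictions` object.
#' @export
snapshot_predict <- function(state, image) {
  if (length(state$ring) < 2) {
    stop("snapshot ring holds fewer than 2 snapshots", call. = FALSE)
  }
  net <- state$teacher
  ensemble_predictions(lapply(state$ring, function(par) {
    net$par <- par
    unet_forward(net, image)$y
  }))
}

#' Compose the final target prediction
#'
#' The target for the consistency loss: the teacher prediction on
#' high-confidence rows plus the refined generator output on
#' low-confidence rows.
#'
#' @param yu Raw teacher prediction.
#' @param part A [row_confidence()] partition.
#' @param g_out Generator output (may be `NULL` when every row is
#'   high-confidence).
#' @return An object of class `target_prediction`: list with `yu`, `yuh`,
#'   `yul`, `ybar` and the partition.
#' @export
compose_targets <- function(yu, part, g_out = NULL) {
  yuh <- yu * part$beta_h_mask
  yul <- if (is.null(g_out)) {
    if (any(part$beta_l > 0)) {
      stop("g_out is required when low-confidence rows exist", call. = FALSE)
    }
    yu * 0
  } else {
    assert_same_shape(yu, g_out, "teacher prediction and generator output")
    g_out * part$beta_l_mask
  }
  structure(list(yu = yu, yuh = yuh, yul = yul, ybar = yuh + yul,
                 partition = part),
            class = "target_prediction")
}

#' Consistency loss against a composed target
#'
#' Pixel-mean squared error between the student prediction on the
#' perturbed unlabeled image and the composed target `ybar`.
#'
#' @param model A [unet_init()] network.
#' @param image_u Unlabeled input matrix.
#' @param target A [compose_targets()] result (or a plain target matrix).
#' @param aug Optional [augment_config()].
#' @param draw Integer keying the perturbation draw.
#' @return Scalar loss.
#' @export
consistency_loss <- function(model, image_u, target, aug = NULL, draw = 1L) {
  ybar <- if (inherits(target, "target_prediction")) target$ybar else target
  assert_same_shape(image_u, ybar, "image and target")
  x <- if (is.null(aug)) image_u else augment(image_u, aug, draw)
  y <- unet_forward(model, x)$y
  mean((y - ybar)^2)
}

all_high_partition <- function(h, w) {
  partition_from_rows(rep(TRUE, h), w)
}

#' Train a segmentation model under one of three regimes
#'
#' * `"supervised"`: minimizes the supervised pixel-MSE on the labeled set
#'   only.
#' * `"mean_teacher"`: adds the consistency loss against raw teacher
#'   predictions on unlabeled images; the teacher is an EMA of the student
#'   updated every optimization step.
#' * `"ours"`: identical to mean teacher during warm-up; once the
#'   validation loss has stabilized, teacher snapshots are taken every
#'   `cadence` epochs, and once the ring holds `ring_k` snapshots each
#'   unlabeled image's target is composed per row: snapshot-ensemble
#'   entropy drives the row-confidence partition, the teacher supplies
#'   high-confidence rows and the trained refiner generator fills
#'   low-confidence rows.
#'
#' Validation follows the cross-center protocol: the unlabeled split's
#' annotated phantoms act as the validation set (their annotations are
#' used for model selection only, never for training), mirroring a study
#' design in which a second center's data provides both the unlabeled
#' pool and the validation set. The validation loss (unperturbed
#' supervised loss) picks the best student weights and triggers
#' snapshotting; without an unlabeled split the labeled set stands in.
#' Deterministic given `seed`.
#'
#' @param regime One of `"supervised"`, `"mean_teacher"`, `"ours"`.
#' @param data A [generate_dataset()] bundle (labeled nonempty; unlabeled
#'   nonempty for the semi-supervised regimes).
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return An object of class `train_state` with `history` (per-epoch
#'   tibble of losses) and best weights.
#' @export
train_segmenter <- function(regime = c("supervised", "mean_teacher", "ours"),
                            data, config = train_config(), seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(inherits(data, "phantom_dataset"), length(data$labeled) >= 1)
  semi <- regime %in% c("mean_teacher", "ours")
  if (semi && !length(data$unlabeled)) {
    stop("semi-supervised regimes need unlabeled data", call. = FALSE)
  }
  if (regime == "ours" && is.null(config$refiner) &&
      !config$force_high_confidence) {
    stop("the `ours` regime needs a trained refiner in the config",
         call. = FALSE)
  }

  state <- new_train_state(config, seed)
  state$regime <- regime
  if (config$epochs == 0) return(state)

  lab_img <- lapply(data$labeled, `[[`, "image")
  lab_msk <- lapply(data$labeled, `[[`, "pectoral_mask")
  unl_img <- lapply(data$unlabeled, `[[`, "image")
  n_lab <- length(lab_img); n_unl <- length(unl_img)
  npx <- length(lab_img[[1]])

  # validation mirrors the cross-center protocol: the second center's
  # annotated data serves as the validation set while its images double
  # as the unlabeled pool; annotations are used for model selection only.
  # Without an unlabeled split, the labeled set stands in.
  if (n_unl > 0) {
    val_img <- unl_img
    val_msk <- lapply(data$unlabeled, `[[`, "pectoral_mask")
  } else {
    val_img <- lab_img
    val_msk <- lab_msk
  }

  # breast conditioning features, one per unlabeled image
  unl_breast <- if (regime == "ours" && !config$force_high_confidence) {
    lapply(unl_img, segment_breast)
  } else {
    NULL
  }

  aug <- config$aug
  aug$seed <- derive_seed(seed, 77L)
  draw <- 0L
  next_draw <- function() {
    draw <<- draw + 1L
    draw
  }
  hist <- vector("list", config$epochs)

  with_local_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      state$epoch <- epoch
      cw <- config$consistency_weight
      if (config$ramp_up > 0 && epoch < config$ramp_up) {
        cw <- cw * exp(-5 * (1 - epoch / config$ramp_up)^2)
      }
      n_steps <- if (semi) max(n_lab, n_unl) else n_lab
      lab_order <- sample(rep_len(sample.int(n_lab), n_steps))
      unl_order <- if (semi) sample(rep_len(sample.int(max(n_unl, 1)),
                                            n_steps)) else integer(0)
      sup_sum <- 0; con_sum <- 0
      refining <- regime == "ours" &&
        (config$force_high_confidence || length(state$ring) >= state$ring_k)

      for (s in seq_len(n_steps)) {
        li <- lab_order[s]
        xs <- augment(lab_img[[li]], aug, next_draw())
        fw <- unet_forward(state$student, xs, keep_cache = TRUE)
        dsup <- 2 * (fw$y - lab_msk[[li]]) / npx
        grads <- unet_backward(state$student, fw$cache, dsup)
        sup_sum <- sup_sum + mean((fw$y - lab_msk[[li]])^2)

        if (semi) {
          ui <- unl_order[s]
          xu <- unl_img[[ui]]
          yu <- teacher_predict(state, xu, aug, next_draw())
          target <- if (refining) {
            if (config$force_high_confidence) {
              compose_targets(yu, all_high_partition(nrow(yu), ncol(yu)))
            } else {
              ens <- snapshot_predict(state, xu)
              est <- do.call(estimate_confidence,
                             c(list(ens), config$uncertainty))
              part <- est$partition
              if (all(part$beta_h == 1)) {
                compose_targets(yu, part)
              } else {
                inp <- generator_input(yu * part$beta_h_mask,
                                       part$beta_h_mask, unl_breast[[ui]])
                compose_targets(yu, part,
                                generator_forward(config$refiner, inp))
              }
            }
          } else {
            compose_targets(yu, all_high_partition(nrow(yu), ncol(yu)))
          }
          xu_s <- augment(xu, aug, next_draw())
          fwu <- unet_forward(state$student, xu_s, keep_cache = TRUE)
          dcon <- cw * 2 * (fwu$y - target$ybar) / npx
          grads <- tree_add(grads,
                            unet_backward(state$student, fwu$cache, dcon))
          con_sum <- con_sum + mean((fwu$y - target$ybar)^2)
        }

        st <- adam_step(state$student$par, grads, state$opt, lr = config$lr)
        state$student$par <- st$par
        state$opt <- st$state
        if (semi) state <- ema_update(state)
      }

      val <- mean(vapply(seq_along(val_img), function(i) {
        supervised_loss(state$student, val_img[[i]], val_msk[[i]])
      }, numeric(1)))
      if (!is.finite(val)) stop("training diverged", call. = FALSE)
      if (val < state$best_val) {
        state$best_val <- val
        state$best_par <- state$student$par
      }
      if (semi) {
        val_t <- mean(vapply(seq_along(val_img), function(i) {
          supervised_loss(state$teacher, val_img[[i]], val_msk[[i]])
        }, numeric(1)))
        if (val_t < state$best_teacher_val) {
          state$best_teacher_val <- val_t
          state$best_teacher_par <- state$teacher$par
        }
      }

      # snapshot ring: starts once the validation loss stabilizes; stores
      # teacher weights for the semi-supervised regimes (the ensemble of
      # Eq.-style snapshot predictions) and student weights for the
      # supervised regime (whose teacher is never EMA-updated)
      prev_min <- if (epoch > 1) min(hist_field(hist, epoch, "val_loss")) else Inf
      if (is.na(state$stabilized_epoch) && epoch > 1 &&
          (prev_min - val) / max(prev_min, 1e-12) < config$stabilize_tol) {
        state$stabilized_epoch <- epoch
      }
      if (!is.na(state$stabilized_epoch) &&
          (epoch - state$stabilized_epoch) %% state$cadence == 0) {
        snap <- if (semi) state$teacher$par else state$student$par
        state$ring <- c(state$ring, list(snap))
        if (length(state$ring) > state$ring_k) {
          state$ring <- tail(state$ring, state$ring_k)
        }
      }

      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, regime = regime,
        sup_loss = sup_sum / n_steps,
        con_loss = if (semi) con_sum / n_steps else NA_real_,
        val_loss = val,
        refining = refining,
        snapshots = length(state$ring))
    }
  })
  state$history <- dplyr::bind_rows(hist)
  state
}

hist_field <- function(hist, upto, field) {
  vapply(hist[seq_len(upto - 1L)], function(h) h[[field]], numeric(1))
}

#' Predict a segmentation mask
#'
#' @param state A `train_state` (or a bare [unet_init()] network).
#' @param image Input matrix.
#' @param weights Which weights to use: `"best"` (validation-best
#'   student, the default for every regime), `"best_teacher"`
#'   (validation-best EMA teacher), `"final"` (last student), or
#'   `"teacher"` (last teacher).
#' @param threshold Binarization threshold on the probability map.
#' @return A list with `prob` (matrix) and `mask` (binary matrix).
#' @export
predict_segmentation <- function(state, image, weights = "best",
                                 threshold = 0.5) {
  net <- if (inherits(state, "unet")) {
    state
  } else {
    switch(weights,
           best = {n <- state$student; n$par <- state$best_par; n},
           best_teacher = {
             n <- state$teacher
             n$par <- state$best_teacher_par
             n
           },
           final = state$student,
           teacher = state$teacher,
           stop("unknown weights selector: ", weights, call. = FALSE))
  }
  prob <- unet_forward(net, image)$y
  list(prob = prob, mask = (prob >= threshold) * 1)
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state: %s, %d epoch(s), best val loss %.4g, %d snapshot(s)>\n",
              x$regime %||% "untrained", x$epoch, x$best_val,
              length(x$ring)))
  invisible(x)
}

#' Tidy the per-epoch training history
#'
#' @param x A `train_state`.
#' @param ... Unused.
#' @return The history tibble (one row per epoch).
#' @export
tidy.train_state <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x A `train_state`.
#' @param ... Unused.
#' @return A tibble with regime, epochs, best validation loss, snapshot
#'   count and stabilization epoch.
#' @export
glance.train_state <- function(x, ...) {
  tibble::tibble(regime = x$regime %||% NA_character_,
                 epochs = x$epoch, best_val_loss = x$best_val,
                 snapshots = length(x$ring),
                 stabilized_epoch = x$stabilized_epoch)
}
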