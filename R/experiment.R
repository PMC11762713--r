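#' Default configuration for the packaged comparison experiment
#'
#' Describes the full phantom-scale study: dataset sizes and samplers,
#' refiner training, and the shared training settings of the three regimes
#' (supervised, mean teacher, uncertainty-aware). The defaults are the
#' desk-scale study conditions; [read_experiment_config()] can override
#' any block from a YAML file.
#'
#' @param n_labeled,n_unlabeled,n_test Split sizes. Labeled phantoms are
#'   sharp; unlabeled and test phantoms carry heavy boundary blur
#'   (emulating a second data center).
#' @param height,width Working resolution.
#' @param refiner_steps Generator updates for refiner pre-training.
#' @param erase_fraction Erased-row fraction range for refiner training.
#' @param epochs,lr,base,levels,ema_decay,consistency_weight,ramp_up,cadence,ring_k
#'   Passed to [train_config()]. The experiment enables the consistency
#'   ramp-up (8 epochs) by default: with a randomly initialized teacher,
#'   full-weight consistency from the first step destabilizes every
#'   semi-supervised regime at this data scale.
#' @param uncertainty List of [estimate_confidence()] arguments.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_labeled = 8, n_unlabeled = 16, n_test = 8,
                              height = 64, width = 64,
                              refiner_steps = 300,
                              erase_fraction = c(0.2, 0.7),
                              epochs = 30, lr = 1e-3, base = 8, levels = 3,
                              ema_decay = 0.99, consistency_weight = 1,
                              ramp_up = 8, cadence = 2, ring_k = 4,
                              uncertainty = list()) {
  structure(list(n_labeled = n_labeled, n_unlabeled = n_unlabeled,
                 n_test = n_test, height = height, width = width,
                 refiner_steps = refiner_steps,
                 erase_fraction = erase_fraction,
                 epochs = epochs, lr = lr, base = base, levels = levels,
                 ema_decay = ema_decay,
                 consistency_weight = consistency_weight,
                 ramp_up = ramp_up, cadence = cadence, ring_k = ring_k,
                 uncertainty = uncertainty),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Unknown fields are rejected with their paths so configuration typos
#' fail loudly.
#'
#' @param path YAML file whose top-level keys match
#'   [experiment_config()] arguments.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- experiment_config()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- modifyList(unclass(defaults), raw)
  class(out) <- "experiment_config"
  out
}

#' Run the three-regime comparison experiment
#'
#' Generates a phantom dataset (sharp labeled phantoms; heavily blurred
#' unlabeled and test phantoms), pre-trains the low-confidence refiner on
#' the labeled annotations, trains the supervised, mean-teacher and
#' uncertainty-aware regimes on identical splits and seeds, and evaluates
#' all three on the test split.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed controlling every random draw.
#' @param out_dir Optional directory: writes the comparison table and
#'   per-regime training logs as CSV, a dataset manifest, a provenance
#'   record (config, seed, package version) and intermediate figures.
#' @return An object of class `pectseg_experiment`: list with `comparison`
#'   (one tibble row per regime), `evaluations`, `states`, `refiner`,
#'   `dataset`, `config`, `seed`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  sampler <- phantom_sampler(height = config$height, width = config$width)
  ds <- generate_dataset(config$n_labeled, config$n_unlabeled, config$n_test,
                         spec_sampler = sampler, seed = derive_seed(seed, 1L))

  ref <- refiner_bundle(height = config$height, width = config$width,
                        seed = derive_seed(seed, 2L))
  ref <- train_refiner(ref,
                       masks = lapply(ds$labeled, `[[`, "pectoral_mask"),
                       breast_masks = lapply(ds$labeled, `[[`, "breast_mask"),
                       steps = config$refiner_steps,
                       erase_fraction = config$erase_fraction,
                       seed = derive_seed(seed, 3L))

  tc <- function(refiner = NULL) {
    train_config(epochs = config$epochs, lr = config$lr, base = config$base,
                 levels = config$levels, ema_decay = config$ema_decay,
                 consistency_weight = config$consistency_weight,
                 ramp_up = config$ramp_up,
                 cadence = config$cadence, ring_k = config$ring_k,
                 aug = augment_config(seed = derive_seed(seed, 4L)),
                 uncertainty = config$uncertainty, refiner = refiner)
  }
  train_seed <- derive_seed(seed, 5L)
  states <- list(
    supervised = train_segmenter("supervised", ds, tc(), train_seed),
    mean_teacher = train_segmenter("mean_teacher", ds, tc(), train_seed),
    ours = train_segmenter("ours", ds, tc(refiner = ref), train_seed))

  truth <- lapply(ds$test, `[[`, "pectoral_mask")
  evaluations <- lapply(states, function(st) {
    preds <- lapply(ds$test, function(ph) {
      predict_segmentation(st, ph$image)$mask
    })
    evaluate_masks(preds, truth)
  })
  comparison <- dplyr::bind_rows(lapply(names(evaluations), function(nm) {
    dplyr::bind_cols(tibble::tibble(regime = nm),
                     summarize_evaluation(evaluations[[nm]]))
  }))

  out <- structure(list(comparison = comparison, evaluations = evaluations,
                        states = states, refiner = ref, dataset = ds,
                        config = config, seed = as.integer(seed)),
                   class = "pectseg_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.pectseg_experiment <- function(x, ...) {
  cat(sprintf("<pectseg_experiment: seed %d>\n", x$seed))
  print(x$comparison)
  invisible(x)
}

#' Tidy the experiment comparison table
#'
#' @param x A `pectseg_experiment`.
#' @param ... Unused.
#' @return The comparison tibble (one row per regime).
#' @export
tidy.pectseg_experiment <- function(x, ...) x$comparison

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(exp$comparison, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)
  for (nm in names(exp$states)) {
    write.csv(tidy(exp$states[[nm]]),
              file.path(out_dir, sprintf("history_%s.csv", nm)),
              row.names = FALSE)
  }
  write.csv(exp$refiner$history, file.path(out_dir, "history_refiner.csv"),
            row.names = FALSE)
  write_dataset(exp$dataset, file.path(out_dir, "dataset"))
  yaml::write_yaml(list(seed = exp$seed,
                        package_version = as.character(
                          utils::packageVersion("pectseg")),
                        config = unclass(exp$config)),
                   file.path(out_dir, "provenance.yaml"))
  write_experiment_figures(exp, out_dir)
  invisible(out_dir)
}

write_experiment_figures <- function(exp, out_dir) {
  fig <- function(name, plot, width = 6, height = 4) {
    ggplot2::ggsave(file.path(out_dir, name), plot,
                    width = width, height = height, dpi = 120)
  }
  ph <- exp$dataset$test[[1]]
  fig("test_phantom.png", ggplot2::autoplot(ph))
  st <- exp$states$ours
  if (length(st$ring) >= 2) {
    ens <- snapshot_predict(st, ph$image)
    est <- do.call(estimate_confidence, c(list(ens), exp$config$uncertainty))
    fig("uncertainty.png", ggplot2::autoplot(est), width = 9)
    part <- est$partition
    yu <- teacher_predict(st, ph$image)
    if (any(part$beta_l > 0)) {
      inp <- generator_input(yu * part$beta_h_mask, part$beta_h_mask,
                             segment_breast(ph$image))
      tgt <- compose_targets(yu, part, generator_forward(exp$refiner, inp))
      fig("refined_target.png", plot_grid_map(tgt$ybar, "composed target"))
    }
  }
  for (nm in names(exp$states)) {
    fig(sprintf("loss_%s.png", nm), ggplot2::autoplot(exp$states[[nm]]))
  }
  invisible(NULL)
}
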