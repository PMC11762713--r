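#' Assemble the generator input
#'
#' Stacks the three aligned conditioning grids of the low-confidence
#' refiner as channels: the high-confidence-masked prediction, the
#' broadcast high-confidence row indicator, and the coarse breast mask.
#'
#' @param yuh High-confidence prediction grid (prediction times
#'   `beta_h_mask`).
#' @param beta_h_mask Rowwise-constant 0/1 indicator grid (or a
#'   `confidence_partition`, whose `beta_h_mask` is used).
#' @param s_breast Binary breast mask.
#' @return A 3-channel array of class `generator_input`.
#' @export
generator_input <- function(yuh, beta_h_mask, s_breast) {
  if (inherits(beta_h_mask, "confidence_partition")) {
    beta_h_mask <- beta_h_mask$beta_h_mask
  }
  assert_same_shape(yuh, beta_h_mask, "generator input channels")
  assert_same_shape(yuh, s_breast, "generator input channels")
  if (any(beta_h_mask != beta_h_mask[, 1])) {
    stop("beta_h_mask must be constant within each row", call. = FALSE)
  }
  structure(stack_channels(yuh, beta_h_mask, s_breast),
            class = "generator_input")
}

#' Run the refiner generator
#'
#' Forward pass of the generator network; deterministic (the network has
#' no stochastic layers). Output is a full-frame probability grid in
#' `[0, 1]`.
#'
#' @param generator A [unet_init()] network with 3 input channels (or a
#'   `refiner_bundle`, whose generator is used).
#' @param inp A [generator_input()].
#' @return Probability matrix of the input's height and width.
#' @export
generator_forward <- function(generator, inp) {
  if (inherits(generator, "refiner_bundle")) generator <- generator$generator
  stopifnot(inherits(generator, "unet"))
  if (dim(as_chan(inp))[3] != generator$in_ch) {
    stop("generator input has wrong channel count", call. = FALSE)
  }
  unet_forward(generator, unclass(inp))$y
}

#' Analytic critic for verification
#'
#' Wraps a closed-form score function and its input gradient in the
#' interface used by [gradient_penalty()] and [wgan_critic_loss()], so the
#' penalty and losses can be checked against critics whose gradients are
#' known exactly (for example a linear functional).
#'
#' @param score `function(x) -> scalar`.
#' @param grad `function(x) -> gradient grid of x's shape`.
#' @return An object of class `analytic_critic`.
#' @export
analytic_critic <- function(score, grad) {
  structure(list(score = score, grad = grad), class = "analytic_critic")
}

critic_score <- function(critic, x) {
  if (inherits(critic, "analytic_critic")) return(critic$score(x))
  critic_forward(critic, x)$value
}

critic_input_gradient <- function(critic, x) {
  if (inherits(critic, "analytic_critic")) return(critic$grad(x))
  fw <- critic_forward(critic, x)
  chan_to_mat(critic_backward(critic, fw$cache, 1)$dx)
}

#' Gradient penalty of the Wasserstein critic
#'
#' Evaluates the critic's input-gradient norm at a random interpolate
#' `alpha * fake + (1 - alpha) * real` (`alpha` uniform, seeded by `draw`)
#' and returns `(||grad||_2 - 1)^2`. The penalty drives the critic toward
#' the unit-gradient-norm functions over which the Wasserstein distance is
#' attained.
#'
#' @param critic A [critic_init()] network or [analytic_critic()].
#' @param real,fake Mask grids of one shape.
#' @param draw Integer seeding the interpolation coefficient.
#' @return Scalar penalty.
#' @export
gradient_penalty <- function(critic, real, fake, draw = 1L) {
  assert_same_shape(real, fake, "real and fake masks")
  alpha <- with_local_seed(derive_seed(20201L, draw), runif(1))
  xhat <- alpha * fake + (1 - alpha) * real
  g <- critic_input_gradient(critic, xhat)
  (sqrt(sum(g^2)) - 1)^2
}

#' Critic (discriminator) loss
#'
#' The Wasserstein-GAN-with-gradient-penalty critic objective as
#' implemented here: `D(fake) - D(real) + lambda_gp * penalty`, which the
#' critic minimizes so that real masks score higher than generated ones
#' while staying close to unit gradient norm.
#'
#' @param critic A [critic_init()] network or [analytic_critic()].
#' @param real,fake Mask grids.
#' @param lambda_gp Gradient-penalty weight (`>= 0`).
#' @param draw Integer seeding the penalty interpolate.
#' @return Scalar loss.
#' @export
wgan_critic_loss <- function(critic, real, fake, lambda_gp = 10, draw = 1L) {
  stopifnot(lambda_gp >= 0)
  loss <- critic_score(critic, fake) - critic_score(critic, real)
  if (lambda_gp > 0) {
    loss <- loss + lambda_gp * gradient_penalty(critic, real, fake, draw)
  }
  loss
}

#' Generator loss
#'
#' `-D(g_out)` plus the high-confidence consistency term: the sum of
#' squared differences between the generator output and the
#' high-confidence prediction over high-confidence rows,
#' `sum((g_out * beta_h - yuh)^2)`. The adversarial term pulls the output
#' toward the annotated-mask distribution (the learned shape prior); the
#' consistency term anchors it to the trusted rows.
#'
#' @param critic A [critic_init()] network or [analytic_critic()].
#' @param g_out Generator output grid.
#' @param part A [row_confidence()] partition.
#' @param yuh High-confidence prediction grid.
#' @return Scalar loss.
#' @export
wgan_generator_loss <- function(critic, g_out, part, yuh) {
  assert_same_shape(g_out, yuh, "generator output and target")
  -critic_score(critic, g_out) + sum((g_out * part$beta_h_mask - yuh)^2)
}

#' Restrict the generator output to low-confidence rows
#'
#' @param g_out Generator output grid.
#' @param part A [row_confidence()] partition.
#' @return `g_out * beta_l_mask`.
#' @export
refine <- function(g_out, part) {
  assert_same_shape(g_out, part$beta_l_mask, "generator output and partition")
  g_out * part$beta_l_mask
}

#' Bundle the refiner networks and their training configuration
#'
#' @param height,width Working grid size (must be divisible by
#'   `2^(levels - 1)` and `2^critic_blocks`).
#' @param base Generator base channel width.
#' @param levels Generator U-Net levels.
#' @param critic_base,critic_blocks Critic capacity.
#' @param lambda_gp Gradient-penalty weight.
#' @param critic_steps Critic updates per generator update.
#' @param lr_g,lr_d Adam learning rates (generator/critic);
#'   `beta1 = 0.5, beta2 = 0.9` as is usual for this training scheme.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `refiner_bundle`.
#' @export
refiner_bundle <- function(height = 64, width = 64, base = 8, levels = 3,
                           critic_base = 8, critic_blocks = 3,
                           lambda_gp = 10, critic_steps = 5,
                           lr_g = 5e-3, lr_d = 5e-3, seed = 1L) {
  stopifnot(lambda_gp >= 0, critic_steps >= 1)
  gen <- unet_init(in_ch = 3, base = base, levels = levels,
                   seed = derive_seed(seed, 1L))
  cri <- critic_init(in_ch = 1, base = critic_base, blocks = critic_blocks,
                     seed = derive_seed(seed, 2L))
  structure(list(generator = gen, critic = cri, lambda_gp = lambda_gp,
                 critic_steps = critic_steps, lr_g = lr_g, lr_d = lr_d,
                 height = height, width = width,
                 opt_g = adam_init(gen$par), opt_d = adam_init(cri$par),
                 history = tibble::tibble(step = integer(),
                                          critic_loss = numeric(),
                                          generator_loss = numeric()),
                 trained_steps = 0L, seed = as.integer(seed)),
            class = "refiner_bundle")
}

#' @export
print.refiner_bundle <- function(x, ...) {
  cat(sprintf("<refiner_bundle: %dx%d, lambda_gp=%g, %d generator steps trained>\n",
              x$height, x$width, x$lambda_gp, x$trained_steps))
  invisible(x)
}

#' Train the low-confidence refiner
#'
#' Adversarial training of the generator against the W-GAN-GP critic on
#' annotated pectoral masks. Each step draws a mask, erases a random
#' fraction of its rows ([erase_rows()]) to emulate partially-confident
#' predictions, and builds the [generator_input()] from the erased mask,
#' the kept-row indicator and the matching breast mask. The critic is
#' updated `critic_steps` times per generator update (real = intact
#' annotated masks, fake = generator output); the generator minimizes
#' [wgan_generator_loss()]. Deterministic given `seed`.
#'
#' @param bundle A [refiner_bundle()].
#' @param masks List of binary pectoral masks (annotations).
#' @param breast_masks List of matching binary breast masks.
#' @param steps Number of generator updates (0 returns the bundle
#'   unchanged).
#' @param erase_fraction Length-2 range; each step's erased-row fraction is
#'   drawn uniformly from it.
#' @param erase_empty_prob Probability that a training input also marks
#'   every empty row of the mask as low-confidence. At inference the
#'   low-confidence region regularly includes rows beyond the wedge with
#'   no muscle at all; the generator must learn that an empty fill is a
#'   valid completion there, which nonempty-row erasures alone never
#'   teach.
#' @param seed Integer seed.
#' @return The trained bundle with an appended loss `history` tibble.
#' @export
train_refiner <- function(bundle, masks, breast_masks, steps = 300,
                          erase_fraction = c(0.2, 0.7),
                          erase_empty_prob = 0.5, seed = 1L) {
  stopifnot(inherits(bundle, "refiner_bundle"), length(masks) >= 1,
            length(masks) == length(breast_masks), steps >= 0)
  if (steps == 0) return(bundle)
  gen <- bundle$generator; cri <- bundle$critic
  opt_g <- bundle$opt_g; opt_d <- bundle$opt_d
  hist <- vector("list", steps)
  n <- length(masks)

  make_input <- function(idx, frac, eseed, drop_empty) {
    er <- erase_rows(masks[[idx]], frac, seed = eseed)
    kept <- er$kept_rows
    if (drop_empty) kept[rowSums(masks[[idx]]) == 0] <- FALSE
    list(inp = generator_input(er$mask,
                               row_broadcast(as.numeric(kept), ncol(er$mask)),
                               breast_masks[[idx]]),
         yuh = er$mask * row_broadcast(as.numeric(kept), ncol(er$mask)),
         part = partition_from_rows(kept, ncol(er$mask)))
  }

  with_local_seed(seed, {
    for (t in seq_len(steps)) {
      d_loss <- NA_real_
      for (j in seq_len(bundle$critic_steps)) {
        ireal <- sample.int(n, 1)
        ifake <- sample.int(n, 1)
        frac <- runif(1, erase_fraction[1], erase_fraction[2])
        mi <- make_input(ifake, frac, sample.int(1e6, 1),
                         runif(1) < erase_empty_prob)
        fake <- as_chan(unet_forward(gen, unclass(mi$inp))$y)
        real <- as_chan(masks[[ireal]])

        fw_f <- critic_forward(cri, fake)
        bw_f <- critic_backward(cri, fw_f$cache, 1)
        fw_r <- critic_forward(cri, real)
        bw_r <- critic_backward(cri, fw_r$cache, -1)

        alpha <- runif(1)
        xhat <- alpha * fake + (1 - alpha) * real
        fw_h <- critic_forward(cri, xhat)
        bw_h <- critic_backward(cri, fw_h$cache, 1)
        gnorm <- sqrt(sum(bw_h$dx^2))
        penalty <- (gnorm - 1)^2
        u <- (2 * (gnorm - 1) / max(gnorm, 1e-12)) * bw_h$dx
        gp <- critic_gp_grads(cri, fw_h$cache, bw_h, u)

        grads <- tree_add(tree_add(bw_f$grads, bw_r$grads),
                          tree_scale(gp, bundle$lambda_gp))
        st <- adam_step(cri$par, grads, opt_d, lr = bundle$lr_d,
                        beta1 = 0.5, beta2 = 0.9)
        cri$par <- st$par; opt_d <- st$state
        d_loss <- fw_f$value - fw_r$value + bundle$lambda_gp * penalty
        if (!is.finite(d_loss)) stop("critic loss diverged", call. = FALSE)
      }

      igen <- sample.int(n, 1)
      frac <- runif(1, erase_fraction[1], erase_fraction[2])
      mi <- make_input(igen, frac, sample.int(1e6, 1),
                       runif(1) < erase_empty_prob)
      fw_g <- unet_forward(gen, unclass(mi$inp), keep_cache = TRUE)
      fake <- as_chan(fw_g$y)
      fw_c <- critic_forward(cri, fake)
      bw_c <- critic_backward(cri, fw_c$cache, 1)
      bh <- mi$part$beta_h_mask
      g_loss <- -fw_c$value + sum((fw_g$y * bh - mi$yuh)^2)
      if (!is.finite(g_loss)) stop("generator loss diverged", call. = FALSE)
      dfake <- -chan_to_mat(bw_c$dx) + 2 * (fw_g$y * bh - mi$yuh) * bh
      ggrads <- unet_backward(gen, fw_g$cache, dfake)
      st <- adam_step(gen$par, ggrads, opt_g, lr = bundle$lr_g,
                      beta1 = 0.5, beta2 = 0.9)
      gen$par <- st$par; opt_g <- st$state

      hist[[t]] <- tibble::tibble(step = bundle$trained_steps + t,
                                  critic_loss = d_loss,
                                  generator_loss = g_loss)
    }
  })
  bundle$generator <- gen; bundle$critic <- cri
  bundle$opt_g <- opt_g; bundle$opt_d <- opt_d
  bundle$history <- dplyr::bind_rows(bundle$history, dplyr::bind_rows(hist))
  bundle$trained_steps <- bundle$trained_steps + steps
  bundle
}

# partition whose high-confidence rows are the kept rows of an erasure
partition_from_rows <- function(kept_rows, width) {
  beta_h <- as.numeric(kept_rows)
  structure(list(row_uncertainty = 1 - beta_h, delta = 0.5,
                 beta_h = beta_h, beta_l = 1 - beta_h,
                 beta_h_mask = row_broadcast(beta_h, width),
                 beta_l_mask = row_broadcast(1 - beta_h, width)),
            class = "confidence_partition")
}

#' Measure erased-row recovery of a trained refiner
#'
#' For each held-out mask, erases a fixed fraction of its rows, runs the
#' generator, and scores the filled rows (threshold 0.5) against the
#' ground truth on the erased rows only. The copy-input baseline scores
#' the erased input on the same rows.
#'
#' @param bundle A trained [refiner_bundle()].
#' @param masks,breast_masks Held-out mask pairs.
#' @param fraction Fraction of rows to erase.
#' @param seed Integer seed for the erasures.
#' @return A tibble with one row per mask: `dice_filled`, `dice_baseline`.
#' @export
refiner_recovery <- function(bundle, masks, breast_masks, fraction = 0.4,
                             seed = 1L) {
  rows <- purrr::map(seq_along(masks), function(i) {
    er <- erase_rows(masks[[i]], fraction, seed = derive_seed(seed, i))
    erased <- which(!er$kept_rows)
    if (!length(erased)) {
      return(tibble::tibble(mask = i, dice_filled = NA_real_,
                            dice_baseline = NA_real_))
    }
    inp <- generator_input(er$mask,
                           row_broadcast(as.numeric(er$kept_rows),
                                         ncol(er$mask)),
                           breast_masks[[i]])
    g <- generator_forward(bundle, inp)
    tibble::tibble(
      mask = i,
      dice_filled = dice((g >= 0.5)[erased, , drop = FALSE] * 1,
                         masks[[i]][erased, , drop = FALSE]),
      dice_baseline = dice(er$mask[erased, , drop = FALSE],
                           masks[[i]][erased, , drop = FALSE]))
  })
  dplyr::bind_rows(rows)
}
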