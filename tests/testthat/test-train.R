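make_tiny_data <- function(n_lab = 2, n_unl = 2, n_test = 1, seed = 5) {
  sampler <- phantom_sampler(height = 16, width = 16, gland_n = 0,
                             noise_sigma = 0.01)
  generate_dataset(n_lab, n_unl, n_test, spec_sampler = sampler, seed = seed)
}

tiny_config <- function(epochs = 2, ...) {
  train_config(epochs = epochs, base = 2, levels = 2,
               aug = augment_config(p_contrast = 0, p_clahe = 0), ...)
}

test_that("EMA update follows the scalar recurrence exactly", {
  P <- asNamespace("pectseg")
  st <- P$new_train_state(tiny_config(ema_decay = 0.9), seed = 1)
  st$teacher$par <- pectseg:::tree_map1(st$teacher$par, function(x) x * 0)
  st$student$par <- pectseg:::tree_map1(st$student$par, function(x) x * 0 + 1)
  st1 <- ema_update(st)
  leaves <- unlist(st1$teacher$par)
  expect_true(all(abs(leaves - 0.1) < 1e-12))
  # decay 0 copies the student; decay 1 freezes the teacher
  st$ema_decay <- 0
  expect_equal(unlist(ema_update(st)$teacher$par),
               unlist(st$student$par))
  st$ema_decay <- 1
  expect_equal(unlist(ema_update(st)$teacher$par),
               unlist(st$teacher$par))
  # geometric convergence: after n steps the gap scales by decay^n
  st$ema_decay <- 0.8
  stn <- st
  for (i in 1:5) stn <- ema_update(stn)
  gap <- unlist(stn$teacher$par) - unlist(st$student$par)
  expect_equal(max(abs(gap + 0 - (-1) * 0.8^5)), 0, tolerance = 1e-12)
})

test_that("supervised and consistency losses match hand-computed cases", {
  net <- unet_init(in_ch = 1, base = 2, levels = 2, seed = 2)
  img <- matrix(0.5, 8, 8)
  lab <- random_mask(8, 8)
  y <- pectseg:::unet_forward(net, img)$y
  expect_equal(supervised_loss(net, img, lab), mean((y - lab)^2))
  # constant-half prediction against binary label gives exactly 0.25
  expect_equal(mean((matrix(0.5, 8, 8) - lab)^2), 0.25)
  # 2x2 worked case: prediction (1,0;0,0) vs label (1,1;0,0) -> 0.25
  expect_equal(mean((matrix(c(1, 0, 0, 0), 2, 2) -
                       matrix(c(1, 0, 1, 0), 2, 2))^2), 0.25)
  # consistency loss is the same formula with ybar as the label
  part <- pectseg:::all_high_partition(8, 8)
  tgt <- compose_targets(matrix(0.3, 8, 8), part)
  expect_equal(consistency_loss(net, img, tgt),
               mean((y - 0.3)^2))
})

test_that("compose_targets conserves and separates row supports", {
  set.seed(41)
  yu <- matrix(runif(48), 8, 6)
  g <- matrix(runif(48), 8, 6)
  part <- pectseg:::partition_from_rows(c(rep(TRUE, 3), rep(FALSE, 5)), 6)
  tp <- compose_targets(yu, part, g)
  expect_equal(tp$ybar, tp$yuh + tp$yul)
  expect_true(all(tp$yuh * part$beta_l_mask == 0))
  expect_true(all(tp$yul * part$beta_h_mask == 0))
  expect_identical(tp$ybar[1:3, ], yu[1:3, ])
  expect_identical(tp$ybar[4:8, ], g[4:8, ])
  # all-high-confidence: pure mean-teacher target
  tp_h <- compose_targets(yu, pectseg:::all_high_partition(8, 6))
  expect_identical(tp_h$ybar, yu)
  # all-low-confidence: pure refiner target
  tp_l <- compose_targets(yu, pectseg:::partition_from_rows(rep(FALSE, 8), 6), g)
  expect_identical(tp_l$ybar, g)
  expect_error(compose_targets(yu, part), "g_out is required")
})

test_that("snapshot ensembles need K >= 2 and are order-insensitive downstream", {
  P <- asNamespace("pectseg")
  st <- P$new_train_state(tiny_config(), seed = 3)
  img <- matrix(runif(256), 16, 16)
  expect_error(snapshot_predict(st, img), "fewer than 2")
  st$ring <- list(st$teacher$par, st$student$par, st$teacher$par)
  ens <- snapshot_predict(st, img)
  expect_equal(dim(ens)[3], 3)
  expect_true(all(ens >= 0 & ens <= 1))
  st2 <- st
  st2$ring <- rev(st$ring)
  expect_equal(pixel_entropy(snapshot_predict(st2, img)),
               pixel_entropy(ens))
})

test_that("zero-epoch training returns an untrained state", {
  ds <- make_tiny_data()
  st <- train_segmenter("supervised", ds, tiny_config(epochs = 0), seed = 2)
  expect_equal(st$epoch, 0)
  expect_equal(nrow(st$history), 0)
})

test_that("training is reproducible and logs finite losses each epoch", {
  ds <- make_tiny_data()
  st1 <- train_segmenter("mean_teacher", ds, tiny_config(), seed = 7)
  st2 <- train_segmenter("mean_teacher", ds, tiny_config(), seed = 7)
  expect_identical(st1$history, st2$history)
  expect_equal(nrow(st1$history), 2)
  expect_true(all(is.finite(st1$history$sup_loss)))
  expect_true(all(is.finite(st1$history$con_loss)))
  expect_true(all(is.finite(st1$history$val_loss)))
  expect_s3_class(tidy(st1), "tbl_df")
  expect_equal(nrow(glance(st1)), 1)
})

test_that("forced all-high-confidence `ours` reproduces mean teacher step for step", {
  ds <- make_tiny_data()
  cfg_mt <- tiny_config(epochs = 3)
  cfg_ours <- tiny_config(epochs = 3, force_high_confidence = TRUE)
  mt <- train_segmenter("mean_teacher", ds, cfg_mt, seed = 9)
  ours <- train_segmenter("ours", ds, cfg_ours, seed = 9)
  expect_equal(ours$history$sup_loss, mt$history$sup_loss)
  expect_equal(ours$history$con_loss, mt$history$con_loss)
  expect_equal(ours$history$val_loss, mt$history$val_loss)
  expect_equal(unlist(ours$student$par), unlist(mt$student$par))
})

test_that("the `ours` regime requires a refiner and unlabeled data", {
  ds <- make_tiny_data()
  expect_error(train_segmenter("ours", ds, tiny_config(), seed = 1),
               "refiner")
  ds0 <- make_tiny_data(n_unl = 0)
  expect_error(train_segmenter("mean_teacher", ds0, tiny_config(), seed = 1),
               "unlabeled")
})

test_that("teacher prediction is gradient-free and matches student at equal weights", {
  P <- asNamespace("pectseg")
  st <- P$new_train_state(tiny_config(), seed = 4)
  img <- matrix(runif(256), 16, 16)
  yt <- teacher_predict(st, img)
  ys <- P$unet_forward(st$student, img)$y
  expect_identical(yt, ys)   # teacher initialized as a copy of the student
  expect_true(all(yt >= 0 & yt <= 1))
})
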