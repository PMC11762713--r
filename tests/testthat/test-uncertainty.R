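test_that("pixel entropy matches the direct formula", {
  # all agree at 1 -> 0; half/half -> log 2; (0.9, 0.7) -> entropy of 0.8
  e <- pixel_entropy(list(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_equal(e, matrix(0, 2, 2))
  e2 <- pixel_entropy(list(matrix(1, 2, 2), matrix(0, 2, 2)))
  expect_equal(e2, matrix(log(2), 2, 2), tolerance = 1e-12)
  e3 <- pixel_entropy(list(matrix(0.9, 1, 1), matrix(0.7, 1, 1)))
  expect_equal(e3[1, 1], -(0.8 * log(0.8) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  expect_equal(round(e3[1, 1], 4), 0.5004)
  expect_error(pixel_entropy(array(0.5, c(2, 2, 1))), "K >= 2")
})

test_that("pixel entropy is invariant to model ordering and bounded", {
  set.seed(7)
  mats <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
  e <- pixel_entropy(mats)
  expect_equal(pixel_entropy(rev(mats)), e)
  expect_true(all(e >= 0 & e <= log(2) + 1e-12))
  expect_equal(e, oracle_entropy(mats), tolerance = 1e-9)
})

test_that("top-hat keeps narrow ridges and suppresses wide plateaus", {
  expect_equal(top_hat(matrix(2, 6, 9), 5), matrix(0, 6, 9))
  ridge <- matrix(0, 5, 11); ridge[, 6] <- 1
  expect_equal(top_hat(ridge, 5), ridge)
  plateau <- matrix(0, 5, 15); plateau[, 4:12] <- 1     # wider than SE
  th <- top_hat(plateau, 5)
  expect_true(all(th[, 6:10] == 0))                     # plateau interior
  expect_equal(th, oracle_top_hat(plateau, 5))
})

test_that("shock filter sharpens a blurred step and respects range bounds", {
  flat <- matrix(0.4, 16, 16)
  expect_equal(cesf(flat), flat)
  ramp <- matrix(rep(1 / (1 + exp(-0.4 * (seq_len(32) - 16))), each = 32),
                 32, 32)
  out <- cesf(ramp, n_iter = 10)
  grad_max <- function(m) max(abs(m[, -1] - m[, -ncol(m)]))
  expect_gte(grad_max(out), grad_max(ramp))
  expect_gte(min(out), min(ramp) - 1e-12)
  expect_lte(max(out), max(ramp) + 1e-12)
})

test_that("select_boundary keeps only the largest 8-connected component", {
  m <- matrix(0, 10, 10)
  m[2:3, 2:6] <- 1          # 10 pixels
  m[8, 8:10] <- 1           # 3 pixels
  out <- select_boundary(m, 0.5)
  expect_equal(sum(out), 10)
  expect_true(all(out[2:3, 2:6] == 1))
  expect_equal(select_boundary(m * 0.1, 0.5), matrix(0, 10, 10))
  one <- matrix(0, 5, 5); one[2:4, 3] <- 1
  expect_equal(select_boundary(one, 0.5), one)
  # diagonal touching counts as one component (8-connectivity)
  diag2 <- matrix(0, 6, 6); diag2[1, 1] <- 1; diag2[2, 2] <- 1
  diag2[5, 5] <- 1
  expect_equal(sum(select_boundary(diag2, 0.5)), 2)
})

test_that("row confidence partitions rows by boundary intersection", {
  b <- matrix(0, 10, 6); b[3:7, 2] <- 1
  part <- row_confidence(b, delta = 0.5)
  expect_equal(which(part$beta_h == 1), 3:7)
  expect_true(all(part$beta_h + part$beta_l == 1))
  expect_equal(part$beta_h_mask[4, ], rep(1, 6))
  expect_equal(part$beta_h_mask[1, ], rep(0, 6))
  full <- row_confidence(matrix(1, 4, 4))
  expect_true(all(full$beta_h == 1))
  none <- row_confidence(matrix(0, 4, 4))
  expect_true(all(none$beta_l == 1))
  tb <- tidy(part)
  expect_equal(nrow(tb), 10)
  expect_equal(tb$beta_h, part$beta_h)
})

test_that("high_confidence_prediction zeroes exactly the low-confidence rows", {
  set.seed(3)
  yu <- matrix(runif(60), 10, 6)
  b <- matrix(0, 10, 6); b[c(1, 4, 9), 3] <- 1
  part <- row_confidence(b)
  yh <- high_confidence_prediction(yu, part)
  expect_identical(yh[c(1, 4, 9), ], yu[c(1, 4, 9), ])
  expect_true(all(yh[-c(1, 4, 9), ] == 0))
})

test_that("the composed estimate routes sharp and disagreeing ensembles correctly", {
  h <- 32; w <- 32
  soft <- function(steep, shift) {
    outer(seq_len(h), seq_len(w), function(r, c) {
      1 / (1 + exp(-steep * ((20 - 0.3 * r + shift) - c)))
    })
  }
  # tight ensemble with a thin entropy ridge at the boundary: every wedge
  # row intersects the ridge -> high confidence
  ens_sharp <- ensemble_predictions(lapply(c(-0.2, 0, 0.2), soft,
                                           steep = 3))
  est <- estimate_confidence(ens_sharp, se_width = 7)
  expect_gt(mean(est$partition$beta_h), 0.9)
  # wildly disagreeing ensemble: wide entropy band, top-hat suppresses it
  ens_wide <- ensemble_predictions(lapply(c(-9, -3, 3, 9), soft,
                                          steep = 0.15))
  est2 <- estimate_confidence(ens_wide, se_width = 7)
  expect_gt(mean(est2$partition$beta_l), mean(est$partition$beta_l))
  # determinism
  est3 <- estimate_confidence(ens_wide, se_width = 7)
  expect_identical(est2$partition$beta_h, est3$partition$beta_h)
})
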