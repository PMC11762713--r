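test_that("phantom generation honors the spec fields and determinism", {
  sp <- phantom_spec(seed = 3, blur_rows = integer(0), noise_sigma = 0,
                     gland_n = 0)
  ph <- generate_phantom(sp)
  expect_true(all(ph$clarity == "sharp"))
  expect_true(all(abs(ph$image[ph$pectoral_mask == 1] -
                        sp$pectoral_level) < 1e-12))
  ph2 <- generate_phantom(sp)
  expect_identical(ph, ph2)
  phn <- generate_phantom(phantom_spec(seed = 4, blur_rows = 10:20))
  expect_equal(unique(phn$clarity[10:20]), "blurred")
  expect_true(all(phn$clarity[-(10:20)] == "sharp"))
})

test_that("degenerate wedges are rejected", {
  expect_error(phantom_spec(pectoral_intercepts = c(200, 20)), "degenerate")
  expect_error(phantom_spec(pectoral_intercepts = c(20, 0)), "degenerate")
  expect_error(phantom_spec(breast_level = 0.9, pectoral_level = 0.8),
               "levels")
})

test_that("masks are nested and rowwise-contiguous for random specs", {
  sampler <- phantom_sampler()
  for (i in 1:12) {
    ph <- generate_phantom(sampler(i, sample(c("labeled", "unlabeled"), 1)))
    expect_true(all(ph$breast_mask[ph$pectoral_mask == 1] == 1))
    ok <- apply(ph$pectoral_mask, 1, function(r) {
      w <- which(r == 1)
      length(w) == 0 || all(w == seq_along(w))
    })
    expect_true(all(ok))
  }
})

test_that("sharp rows have a larger cross-boundary step than blurred rows", {
  sp <- phantom_spec(seed = 9, blur_rows = 15:30, noise_sigma = 0,
                     gland_n = 0)
  ph <- generate_phantom(sp)
  step_at <- function(r) {
    edge <- max(which(ph$pectoral_mask[r, ] == 1))
    abs(ph$image[r, edge] - ph$image[r, edge + 1])
  }
  rl <- sp$pectoral_intercepts[2]
  sharp <- setdiff(seq_len(rl - 2)[-(1:2)], 15:30)
  expect_true(min(vapply(sharp, step_at, 1)) >
                max(vapply(15:30, step_at, 1)))
})

test_that("dataset splits are disjoint seed streams with the right sizes", {
  ds <- generate_dataset(0, 0, 5, seed = 2)
  expect_length(ds$labeled, 0)
  expect_length(ds$test, 5)
  ds2 <- generate_dataset(0, 0, 5, seed = 2)
  expect_identical(ds, ds2)
  ds3 <- generate_dataset(10, 20, 10, seed = 5)
  imgs <- c(ds3$labeled, ds3$unlabeled, ds3$test)
  expect_length(unique(lapply(imgs, `[[`, "image")), 40)
  # unlabeled split carries systematically more blur
  blur_frac <- function(phs) {
    mean(vapply(phs, function(p) mean(p$clarity == "blurred"), 1))
  }
  expect_gt(blur_frac(ds3$unlabeled), blur_frac(ds3$labeled))
})

test_that("erase_rows zeroes the requested fraction of nonempty rows", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  m <- ph$pectoral_mask
  e0 <- erase_rows(m, 0, seed = 1)
  expect_identical(e0$mask, m)
  expect_true(all(e0$kept_rows))
  e1 <- erase_rows(m, 1, seed = 1)
  expect_equal(sum(e1$mask), 0)
  # 10 nonempty rows, fraction 0.5 -> exactly 5 erased
  m10 <- matrix(0, 20, 8); m10[6:15, 1:3] <- 1
  e5 <- erase_rows(m10, 0.5, seed = 7)
  erased <- which(!e5$kept_rows)
  expect_length(erased, 5)
  expect_true(all(e5$mask[erased, ] == 0))
  kept <- which(e5$kept_rows)
  expect_identical(e5$mask[kept, ], m10[kept, ])
  # empty mask unchanged
  ez <- erase_rows(matrix(0, 4, 4), 0.8, seed = 1)
  expect_true(all(ez$kept_rows))
})

test_that("write_dataset produces PNGs and a manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(1, 1, 1, seed = 3)
  mf <- write_dataset(ds, dir)
  expect_equal(nrow(mf), 3)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(all(file.exists(file.path(dir, mf$path))))
})
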