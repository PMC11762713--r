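# finite-difference verification of the hand-written network gradients

fd_grad <- function(lossfun, flat, skeleton, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    a <- flat; a[i] <- a[i] + eps
    b <- flat; b[i] <- b[i] - eps
    (lossfun(relist(a, skeleton)) - lossfun(relist(b, skeleton))) / (2 * eps)
  }, numeric(1))
}

test_that("U-Net backward matches finite differences", {
  P <- asNamespace("pectseg")
  set.seed(21)
  net <- unet_init(in_ch = 1, base = 2, levels = 2, seed = 3)
  x <- matrix(runif(64), 8, 8)
  lab <- random_mask(8, 8)
  fw <- P$unet_forward(net, x, keep_cache = TRUE)
  g <- unlist(P$unet_backward(net, fw$cache, 2 * (fw$y - lab) / 64))
  lossfun <- function(par) {
    n <- net; n$par <- par
    mean((P$unet_forward(n, x)$y - lab)^2)
  }
  flat <- unlist(net$par)
  idx <- sample(length(flat), 25)
  expect_equal(fd_grad(lossfun, flat, net$par, idx), unname(g[idx]),
               tolerance = 1e-5)
})

test_that("critic backward matches finite differences for weights and input", {
  P <- asNamespace("pectseg")
  set.seed(22)
  cri <- critic_init(in_ch = 1, base = 2, blocks = 2, seed = 5)
  cx <- array(runif(64), c(8, 8, 1))
  fw <- P$critic_forward(cri, cx)
  bw <- P$critic_backward(cri, fw$cache, 1)
  flat <- unlist(cri$par)
  vfun <- function(par) {
    cc <- cri; cc$par <- par
    P$critic_forward(cc, cx)$value
  }
  idx <- sample(length(flat), 20)
  expect_equal(fd_grad(vfun, flat, cri$par, idx), unname(unlist(bw$grads)[idx]),
               tolerance = 1e-5)
  xin <- as.numeric(cx)
  ii <- sample(64, 15)
  fdx <- vapply(ii, function(i) {
    a <- xin; a[i] <- a[i] + 1e-6
    b <- xin; b[i] <- b[i] - 1e-6
    (P$critic_forward(cri, array(a, c(8, 8, 1)))$value -
       P$critic_forward(cri, array(b, c(8, 8, 1)))$value) / 2e-6
  }, numeric(1))
  expect_equal(fdx, as.numeric(bw$dx)[ii], tolerance = 1e-5)
})

test_that("gradient-penalty double backprop matches finite differences", {
  P <- asNamespace("pectseg")
  set.seed(23)
  cri <- critic_init(in_ch = 1, base = 2, blocks = 2, seed = 7)
  cx <- array(runif(64), c(8, 8, 1))
  penfun <- function(par) {
    cc <- cri; cc$par <- par
    fw <- P$critic_forward(cc, cx)
    bw <- P$critic_backward(cc, fw$cache, 1)
    (sqrt(sum(bw$dx^2)) - 1)^2
  }
  fw <- P$critic_forward(cri, cx)
  bw <- P$critic_backward(cri, fw$cache, 1)
  gn <- sqrt(sum(bw$dx^2))
  u <- (2 * (gn - 1) / gn) * bw$dx
  gp <- unlist(P$critic_gp_grads(cri, fw$cache, bw, u))
  flat <- unlist(cri$par)
  idx <- sample(length(flat), 20)
  expect_equal(fd_grad(penfun, flat, cri$par, idx), unname(gp[idx]),
               tolerance = 1e-4)
})

test_that("Adam moves parameters against the gradient and is deterministic", {
  P <- asNamespace("pectseg")
  par <- list(w = matrix(1, 2, 2), b = c(0, 0))
  g <- list(w = matrix(0.5, 2, 2), b = c(-1, 1))
  st <- P$adam_init(par)
  out1 <- P$adam_step(par, g, st, lr = 0.1)
  expect_true(all(out1$par$w < par$w))
  expect_true(out1$par$b[1] > 0 && out1$par$b[2] < 0)
  out2 <- P$adam_step(par, g, st, lr = 0.1)
  expect_identical(out1$par, out2$par)
})
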