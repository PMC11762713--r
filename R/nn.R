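# Hand-written convolutional networks.
#
# Parameters are nested lists whose leaves are numeric (conv weight matrix
# `w` of shape (Cout, k*k*Cin) and bias vector `b`); architecture metadata
# lives alongside the parameter tree so generic tree operations (Adam, EMA)
# can walk the leaves uniformly. Convolutions are cross-correlations with
# "same" zero padding, computed in C++ (see src/convnet.cpp).

new_conv <- function(cin, cout, k) {
  list(w = matrix(rnorm(cout * k * k * cin, sd = sqrt(2 / (k * k * cin))),
                  nrow = cout),
       b = numeric(cout))
}

conv_fw <- function(x, layer, k) .nn_conv_fw(x, layer$w, layer$b, k)

conv_bw_input <- function(dy, layer, k) {
  .nn_conv_bw_input(dy, layer$w, k, ncol(layer$w) %/% (k * k))
}

conv_bw_weights <- function(x, dy, k) {
  list(w = .nn_conv_bw_weights(x, dy, k),
       b = colSums(matrix(dy, ncol = dim(dy)[3])))
}

relu_fw <- function(z) list(a = pmax(z, 0), mask = (z > 0) * 1)
lrelu_fw <- function(z, alpha = 0.2) {
  mask <- ifelse(z > 0, 1, alpha)
  list(a = z * mask, mask = mask)
}
sigmoid <- function(z) 1 / (1 + exp(-z))

pool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  io <- seq(1, h, 2); jo <- seq(1, w, 2)
  0.25 * (x[io, jo, , drop = FALSE] + x[io + 1, jo, , drop = FALSE] +
          x[io, jo + 1, , drop = FALSE] + x[io + 1, jo + 1, , drop = FALSE])
}

pool2_bw <- function(dy) {
  h2 <- dim(dy)[1]; w2 <- dim(dy)[2]
  dy[rep(seq_len(h2), each = 2), rep(seq_len(w2), each = 2), ,
     drop = FALSE] / 4
}

up2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2), ,
    drop = FALSE]
}

up2_bw <- function(dy) 4 * pool2(dy)

# ---- parameter-tree utilities --------------------------------------------

tree_map1 <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map1, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_zeros <- function(a) tree_map1(a, function(x) x * 0)

tree_add <- function(a, b) tree_map2(a, b, `+`)

tree_scale <- function(a, s) tree_map1(a, function(x) x * s)

tree_norm <- function(a) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + sum(x^2)
    invisible(NULL)
  }
  walk(a)
  sqrt(tot)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(par) list(m = tree_zeros(par), v = tree_zeros(par), t = 0L)

adam_step <- function(par, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(st$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  st$v <- tree_map2(st$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  upd <- tree_map2(st$m, st$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  list(par = tree_map2(par, upd, `-`), state = st)
}

# ---- U-Net ---------------------------------------------------------------

#' Initialize a small U-Net segmentation network
#'
#' Encoder-decoder with skip connections: `levels - 1` encoder blocks
#' (3x3 conv + ReLU + 2x2 average pool), a bottleneck conv, matching
#' decoder blocks (nearest-neighbor upsampling, skip concatenation, 3x3
#' conv + ReLU) and a 1x1 output conv squashed through a sigmoid so the
#' output is a per-pixel foreground probability of the input's shape.
#'
#' @param in_ch Input channels (1 for images, 3 for the refiner input).
#' @param base Base channel width; deeper levels double it.
#' @param levels Number of resolution levels (`>= 2`); input height and
#'   width must be divisible by `2^(levels - 1)`.
#' @param seed Integer seed for weight initialization (He-normal).
#' @return An object of class `unet`.
#' @export
unet_init <- function(in_ch = 1, base = 8, levels = 3, seed = 1L) {
  stopifnot(levels >= 2, base >= 1)
  ch <- base * 2^(seq_len(levels - 1) - 1)
  par <- with_local_seed(seed, {
    enc <- vector("list", levels - 1)
    cin <- in_ch
    for (i in seq_len(levels - 1)) {
      enc[[i]] <- new_conv(cin, ch[i], 3)
      cin <- ch[i]
    }
    bott <- new_conv(ch[levels - 1], base * 2^(levels - 1), 3)
    dec <- vector("list", levels - 1)
    below <- base * 2^(levels - 1)
    for (i in rev(seq_len(levels - 1))) {
      dec[[i]] <- new_conv(below + ch[i], ch[i], 3)
      below <- ch[i]
    }
    list(enc = enc, bott = bott, dec = dec, out = new_conv(ch[1], 1, 1))
  })
  structure(list(par = par, in_ch = in_ch, base = base, levels = levels),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  np <- 0
  tree_map1(x$par, function(p) {np <<- np + length(p); p})
  cat(sprintf("<unet: %d levels, base %d, %d input channel(s), %d parameters>\n",
              x$levels, x$base, x$in_ch, np))
  invisible(x)
}

unet_forward <- function(net, x, keep_cache = FALSE) {
  par <- net$par
  L <- net$levels
  x <- as_chan(x)
  stopifnot(dim(x)[1] %% 2^(L - 1) == 0, dim(x)[2] %% 2^(L - 1) == 0,
            dim(x)[3] == net$in_ch)
  enc_in <- vector("list", L - 1); enc_a <- vector("list", L - 1)
  enc_m <- vector("list", L - 1)
  cur <- x
  for (i in seq_len(L - 1)) {
    enc_in[[i]] <- cur
    r <- relu_fw(conv_fw(cur, par$enc[[i]], 3))
    enc_a[[i]] <- r$a; enc_m[[i]] <- r$mask
    cur <- pool2(r$a)
  }
  bott_in <- cur
  rb <- relu_fw(conv_fw(cur, par$bott, 3))
  cur <- rb$a
  dec_in <- vector("list", L - 1); dec_m <- vector("list", L - 1)
  for (i in rev(seq_len(L - 1))) {
    cmb <- stack_channels(up2(cur), enc_a[[i]])
    dec_in[[i]] <- cmb
    r <- relu_fw(conv_fw(cmb, par$dec[[i]], 3))
    dec_m[[i]] <- r$mask
    cur <- r$a
  }
  zo <- conv_fw(cur, par$out, 1)
  y <- sigmoid(chan_to_mat(zo))
  if (!keep_cache) return(list(y = y))
  list(y = y, cache = list(enc_in = enc_in, enc_m = enc_m,
                           bott_in = bott_in, bott_m = rb$mask,
                           dec_in = dec_in, dec_m = dec_m,
                           out_in = cur, y = y))
}

# dy: matrix of dLoss/dy; returns parameter-tree gradients
unet_backward <- function(net, cache, dy) {
  par <- net$par
  L <- net$levels
  y <- cache$y
  dzo <- as_chan(dy * y * (1 - y))
  g <- list(enc = vector("list", L - 1), bott = NULL,
            dec = vector("list", L - 1), out = NULL)
  g$out <- conv_bw_weights(cache$out_in, dzo, 1)
  dcur <- conv_bw_input(dzo, par$out, 1)
  dskip <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    dzd <- dcur * cache$dec_m[[i]]
    g$dec[[i]] <- conv_bw_weights(cache$dec_in[[i]], dzd, 3)
    dcmb <- conv_bw_input(dzd, par$dec[[i]], 3)
    ch_up <- dim(dcmb)[3] - dim(cache$enc_m[[i]])[3]
    dskip[[i]] <- dcmb[, , ch_up + seq_len(dim(cache$enc_m[[i]])[3]),
                       drop = FALSE]
    dcur <- up2_bw(dcmb[, , seq_len(ch_up), drop = FALSE])
  }
  dzb <- dcur * cache$bott_m
  g$bott <- conv_bw_weights(cache$bott_in, dzb, 3)
  dcur <- conv_bw_input(dzb, par$bott, 3)
  for (i in rev(seq_len(L - 1))) {
    da <- pool2_bw(dcur) + dskip[[i]]
    dz <- da * cache$enc_m[[i]]
    g$enc[[i]] <- conv_bw_weights(cache$enc_in[[i]], dz, 3)
    dcur <- conv_bw_input(dz, par$enc[[i]], 3)
  }
  g
}

# ---- critic --------------------------------------------------------------

#' Initialize the W-GAN critic
#'
#' A convolutional stack (3x3 conv + leaky ReLU + 2x2 average pool per
#' block) followed by a 1x1 conv to one channel and a spatial mean, giving
#' an unsquashed scalar score. No output squashing is applied, as required
#' for a Wasserstein critic.
#'
#' @param in_ch Input channels.
#' @param base Base channel width.
#' @param blocks Number of conv/pool blocks; input height and width must be
#'   divisible by `2^blocks`.
#' @param seed Integer seed.
#' @return An object of class `critic`.
#' @export
critic_init <- function(in_ch = 1, base = 8, blocks = 3, seed = 1L) {
  stopifnot(blocks >= 1)
  par <- with_local_seed(seed, {
    conv <- vector("list", blocks)
    cin <- in_ch
    for (i in seq_len(blocks)) {
      conv[[i]] <- new_conv(cin, base * 2^(i - 1), 3)
      cin <- base * 2^(i - 1)
    }
    list(conv = conv, head = new_conv(cin, 1, 1))
  })
  structure(list(par = par, in_ch = in_ch, base = base, blocks = blocks,
                 alpha = 0.2), class = "critic")
}

critic_forward <- function(net, x) {
  x <- as_chan(x)
  stopifnot(dim(x)[1] %% 2^net$blocks == 0, dim(x)[2] %% 2^net$blocks == 0)
  nb <- net$blocks
  ins <- vector("list", nb); masks <- vector("list", nb)
  cur <- x
  for (l in seq_len(nb)) {
    ins[[l]] <- cur
    r <- lrelu_fw(conv_fw(cur, net$par$conv[[l]], 3), net$alpha)
    masks[[l]] <- r$mask
    cur <- pool2(r$a)
  }
  h <- conv_fw(cur, net$par$head, 1)
  list(value = mean(h), cache = list(ins = ins, masks = masks,
                                     head_in = cur, h_dim = dim(h)))
}

# standard backprop; seed `dvalue` is dLoss/dvalue. Always also returns the
# input gradient and the per-layer dz maps needed for the gradient-penalty
# double backprop.
critic_backward <- function(net, cache, dvalue = 1) {
  nb <- net$blocks
  hd <- cache$h_dim
  dh <- array(dvalue / (hd[1] * hd[2]), dim = hd)
  g <- list(conv = vector("list", nb), head = NULL)
  g$head <- conv_bw_weights(cache$head_in, dh, 1)
  dcur <- conv_bw_input(dh, net$par$head, 1)
  dzs <- vector("list", nb)
  for (l in rev(seq_len(nb))) {
    da <- pool2_bw(dcur)
    dz <- da * cache$masks[[l]]
    dzs[[l]] <- dz
    g$conv[[l]] <- conv_bw_weights(cache$ins[[l]], dz, 3)
    dcur <- conv_bw_input(dz, net$par$conv[[l]], 3)
  }
  list(grads = g, dx = dcur, dzs = dzs, dh = dh)
}

# Double backprop for the gradient penalty: given u = dPenalty/dg where
# g = critic input gradient, accumulate dPenalty/dW. Activation masks are
# held fixed (the a.e. derivative of the piecewise-linear network), so the
# input-gradient chain is linear in the weights and its adjoint reuses the
# forward conv primitives. Biases do not enter g and get zero gradients.
critic_gp_grads <- function(net, cache, bw, u) {
  nb <- net$blocks
  g <- tree_zeros(net$par)
  t <- as_chan(u)
  for (l in seq_len(nb)) {
    gw <- .nn_conv_bw_weights(t, bw$dzs[[l]], 3)
    g$conv[[l]]$w <- g$conv[[l]]$w + gw
    t <- .nn_conv_fw(t, net$par$conv[[l]]$w,
                     numeric(nrow(net$par$conv[[l]]$w)), 3)
    t <- t * cache$masks[[l]]
    t <- pool2(t)
  }
  g$head$w <- g$head$w + .nn_conv_bw_weights(t, bw$dh, 1)
  g
}
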