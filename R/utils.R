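# shared internal helpers

# run expr with a temporarily-seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# derive a child seed from (seed, draw) without touching the global stream;
# double arithmetic keeps the product exact (< 2^53) before the modulus
derive_seed <- function(seed, draw) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(draw) * 40503) %%
               2147480009)
}

# gblur whose brush never exceeds the image (EBImage requires filter <= image)
safe_gblur <- function(x, sigma) {
  radius <- 2 * ceiling(3 * sigma) + 1
  maxr <- min(dim(x))
  if (radius > maxr) radius <- maxr - (maxr %% 2 == 0)
  EBImage::gblur(x, sigma = sigma, radius = radius)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary <- function(x) all(x %in% c(0, 1))

assert_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) {
    stop(sprintf("%s must share one shape (got %s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# matrix <-> single-channel array
as_chan <- function(x) {
  if (length(dim(x)) == 3L) return(x)
  array(x, dim = c(nrow(x), ncol(x), 1L))
}

chan_to_mat <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(x[, , 1L], nrow = dim(x)[1L])
}

# stack matrices/arrays along the channel dimension
stack_channels <- function(...) {
  parts <- lapply(list(...), as_chan)
  h <- dim(parts[[1L]])[1L]
  w <- dim(parts[[1L]])[2L]
  for (p in parts) assert_same_shape(p[, , 1L], parts[[1L]][, , 1L], "channels")
  array(unlist(parts, use.names = FALSE),
        dim = c(h, w, sum(vapply(parts, function(p) dim(p)[3L], 1L))))
}

# broadcast a per-row indicator to a full grid
row_broadcast <- function(indicator, width) {
  matrix(rep(as.numeric(indicator), times = width),
         nrow = length(indicator), ncol = width)
}
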