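# Independent brute-force references. Each one follows the mathematical
# definition directly (explicit loops / set arithmetic), sharing no code
# with the package implementation it checks.

oracle_dice <- function(a, b) {
  ia <- which(a == 1)
  ib <- which(b == 1)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

oracle_iou <- function(a, b) {
  ia <- which(a == 1)
  ib <- which(b == 1)
  if (length(union(ia, ib)) == 0) return(1)
  length(intersect(ia, ib)) / length(union(ia, ib))
}

oracle_hausdorff <- function(a, b) {
  pa <- which(a == 1, arr.ind = TRUE)
  pb <- which(b == 1, arr.ind = TRUE)
  d <- function(p, q) {  # directed: max over p of min over q
    max(vapply(seq_len(nrow(p)), function(i) {
      min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
    }, numeric(1)))
  }
  max(d(pa, pb), d(pb, pa))
}

oracle_entropy <- function(prob_list) {
  h <- nrow(prob_list[[1]]); w <- ncol(prob_list[[1]])
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    p <- mean(vapply(prob_list, function(m) m[i, j], numeric(1)))
    e <- 0
    if (p > 0) e <- e - p * log(p)
    if (p < 1) e <- e - (1 - p) * log(1 - p)
    out[i, j] <- e
  }
  out
}

# white top-hat with a flat horizontal line SE, border-clipped windows
oracle_top_hat <- function(m, se) {
  h <- nrow(m); w <- ncol(m)
  pl <- (se - 1) %/% 2
  pr <- se - 1 - pl
  ero <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ero[i, j] <- min(m[i, max(1, j - pl):min(w, j + pr)])
  }
  opn <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    opn[i, j] <- max(ero[i, max(1, j - pr):min(w, j + pl)])
  }
  pmax(m - opn, 0)
}

# 8-connected components by repeated flood fill, largest kept
oracle_largest_component <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (bin[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              bin[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue <- c(queue, list(c(ni, nj)))
          }
        }
      }
    }
  }
  if (cur == 0L) return(bin * 0)
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  (lab == which.max(sizes)) * 1
}

oracle_row_confidence <- function(boundary, delta) {
  h <- nrow(boundary)
  pi_row <- numeric(h)
  for (i in seq_len(h)) pi_row[i] <- if (any(boundary[i, ] > 0)) 0 else 1
  list(pi_row = pi_row,
       beta_h = as.numeric(pi_row < delta),
       beta_l = as.numeric(pi_row >= delta))
}

random_mask <- function(h, w, p = 0.3) {
  matrix(rbinom(h * w, 1, p), h, w)
}
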