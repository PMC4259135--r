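# Independent brute-force oracles used to cross-check the vectorised
# implementations.  These deliberately share no code with the package:
# everything is written as direct per-pixel loops over the defining
# formulas.

# Neighbour index with the pipeline's boundary rules: columns wrap,
# rows clamp at the border (zero-flux).
oracle_neighbor <- function(px, i, j, dr, dc) {
  n <- nrow(px); m <- ncol(px)
  ii <- min(max(i + dr, 1L), n)
  jj <- ((j - 1L + dc) %% m) + 1L
  px[ii, jj]
}

# One normal (4-neighbour) Perona-Malik step, per-pixel loop.
oracle_pmd_normal <- function(px, K, lambda) {
  out <- px
  offs <- list(c(-1, 0), c(1, 0), c(0, 1), c(0, -1))
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    acc <- 0
    for (o in offs) {
      d <- oracle_neighbor(px, i, j, o[1], o[2]) - px[i, j]
      acc <- acc + d / (1 + (abs(d) / K)^2)
    }
    out[i, j] <- px[i, j] + lambda / 4 * acc
  }
  out
}

# One modified (8-direction) step, per-pixel loop.
oracle_pmd_modified <- function(px, K, lam) {
  out <- px
  offs <- list(N = c(-1, 0), S = c(1, 0), E = c(0, 1), W = c(0, -1),
               NE = c(-1, 1), NW = c(-1, -1), SE = c(1, 1), SW = c(1, -1))
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    acc <- 0
    for (k in names(offs)) {
      o <- offs[[k]]
      d <- oracle_neighbor(px, i, j, o[1], o[2]) - px[i, j]
      acc <- acc + lam[[k]] * d / (1 + (abs(d) / K)^2)
    }
    out[i, j] <- px[i, j] + acc / 8
  }
  out
}

# Per-pixel separability map by direct summation over the window.
oracle_sep_map <- function(px, h, w, weighted, i_max = max(px)) {
  n <- nrow(px); m <- ncol(px)
  if (i_max <= 0) i_max <- 1
  half <- (w - 1) %/% 2
  vals <- matrix(0, n, m)
  for (i in seq_len(n)) {
    if (i - h < 1 || i + h - 1 > n) next
    for (j in seq_len(m)) {
      cols <- ((j - 1 + (-half:half)) %% m) + 1
      A <- px[(i - h):(i - 1), cols, drop = FALSE]
      B <- px[i:(i + h - 1), cols, drop = FALSE]
      allv <- c(A, B)
      ibar <- mean(allv)
      num <- h * w * ((mean(A) - ibar)^2 + (mean(B) - ibar)^2)
      den <- sum((allv - ibar)^2)
      eta <- if (den > 0) num / den else 0
      eta <- min(max(eta, 0), 1)
      if (weighted) {
        eta <- eta * max((i_max - mean(A)) / i_max, 0) * (mean(B) / i_max)^2
        eta <- min(max(eta, 0), 1)
      }
      vals[i, j] <- eta
    }
  }
  vals
}

# Random test image with speckle-like positive intensities.
random_image <- function(n, m, lo = 0, hi = 255) {
  matrix(runif(n * m, lo, hi), n, m)
}

# Clean two-ridge separability-like map used by seeding tests.
two_ridge_map <- function(n = 128, m = 64, r1 = 40, r2 = 80,
                          v1 = 0.6, v2 = 0.9) {
  vals <- matrix(0, n, m)
  vals[r1, ] <- v1
  vals[r2, ] <- v2
  structure(list(values = vals,
                 window = separability_window(2, 3),
                 i_max_used = 1, weighted = TRUE),
            class = "separability_map")
}

# Exact 90-degree rotation of a square matrix about its centre:
# new[i, j] = old[j, N + 1 - i].
rot90_square <- function(px) {
  n <- nrow(px)
  stopifnot(n == ncol(px))
  out <- px
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- px[j, n + 1 - i]
  out
}
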