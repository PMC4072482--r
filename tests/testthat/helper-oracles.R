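# Shared fixtures and independent oracles used across tests.

dice_coef <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Naive triple-loop 3x3x3 adjacency count: the brute-force oracle for
# imat_imct_adjacency.
brute_adjacency <- function(imat, imct) {
  d <- dim(imat)
  idx <- which(imat, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(n_imat = 0L, n_with = 0L, percentage = 0))
  n_with <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    found <- FALSE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (imct[ii, jj, kk]) { found <- TRUE; break }
    }
    if (found) n_with <- n_with + 1L
  }
  list(n_imat = nrow(idx), n_with = n_with,
       percentage = 100 * n_with / nrow(idx))
}

# Small, fast phantom spec for unit tests.
small_spec <- function(seed = 1L, ...) {
  phantom_spec(seed = seed, ...)
}

# A flat "volume" wrapper for quick construction in tests.
vol3 <- function(data, spacing = c(1, 1, 1), ...) {
  image_volume(data, spacing, ...)
}
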