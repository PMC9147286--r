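# small array helpers for reassembly checks

abind_cols <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2] + dim(b)[2], dim(a)[3]))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}

abind_rows <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# brute-force local maxima: strictly-largest-or-equal within the 8-neighbourhood
brute_local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- NULL
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    ok <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      r2 <- r + dy; c2 <- cc + dx
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w && m[r2, c2] > m[r, cc]) ok <- FALSE
    }
    if (ok) out <- rbind(out, c(r, cc))
  }
  out
}

# a confidence-like map with Gaussian bumps at given (row, col) centres
bump_map <- function(h, w, centres, sigma = 1.2, amp = 1) {
  m <- matrix(0, h, w)
  for (k in seq_len(nrow(centres))) {
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      m[r, cc] <- m[r, cc] +
        amp * exp(-((r - centres[k, 1])^2 + (cc - centres[k, 2])^2) / (2 * sigma^2))
    }
  }
  m
}
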