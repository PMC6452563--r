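# Brute-force oracle: build the periodized analysis operator as an explicit
# matrix (rows are even-shifted reversed filters) and apply it recursively.
oracle_step_matrix <- function(n, filt) {
  A <- matrix(0, n / 2, n)
  for (k in 0:(n / 2 - 1)) {
    for (m in seq_along(filt)) {
      j <- (2 * k + 1 - (m - 1)) %% n
      A[k + 1, j + 1] <- A[k + 1, j + 1] + filt[m]
    }
  }
  A
}

oracle_wpt <- function(x, wavelet, depth) {
  f <- hdsemgsel:::wavelet_filters(wavelet)
  nodes <- list(x)
  for (j in seq_len(depth)) {
    nxt <- list()
    for (nd in nodes) {
      A <- oracle_step_matrix(length(nd), f$lo)
      D <- oracle_step_matrix(length(nd), f$hi)
      nxt <- c(nxt, list(drop(A %*% nd)), list(drop(D %*% nd)))
    }
    nodes <- nxt
  }
  nodes
}
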