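# Shared helpers: tiny CSV writers and a brute-force equal-split allocator
# used as an independent oracle for the balanced method under binary weights.

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Equal-split oracle: under binary weights, each center splits its
# population equally among the facilities it can reach; each facility then
# splits its level of service equally among the centers that reach it.
equal_split_oracle <- function(P, S, B) {
  n <- nrow(B); m <- ncol(B)
  D <- numeric(m)
  for (i in seq_len(n)) {
    k <- sum(B[i, ] > 0)
    if (k > 0) for (j in seq_len(m)) if (B[i, j] > 0) D[j] <- D[j] + P[i] / k
  }
  L <- ifelse(D > 0, S / D, 0)
  A <- numeric(n)
  for (j in seq_len(m)) {
    k <- sum(B[, j] > 0)
    if (k > 0) for (i in seq_len(n)) if (B[i, j] > 0) A[i] <- A[i] + L[j] / k
  }
  list(demand = D, los = L, accessibility = A)
}

# random binary weight matrix in which every row and column has at least
# one positive entry (full coverage)
random_covered_binary <- function(n, m) {
  repeat {
    B <- matrix(rbinom(n * m, 1, 0.5), n, m)
    if (all(rowSums(B) > 0) && all(colSums(B) > 0)) return(B)
  }
}
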