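# Independent oracles, deliberately naive: dense matrices, totals recomputed
# from scratch at every step, explicit interval scans.

# Brute-force greedy core-area removal. V: n_cells x n_features dense value
# matrix (0 where a feature is absent); land: linear cell indices to rank.
# Returns land cells in removal order; ties by lowest cell index.
oracle_caz_order <- function(V, w, land) {
  retained <- land
  out <- integer(0)
  while (length(retained) > 0) {
    Q <- colSums(V[retained, , drop = FALSE])
    use <- which(w > 0 & Q > 0)
    delta <- vapply(retained, function(i) {
      if (length(use) == 0) return(0)
      max(w[use] * V[i, use] / Q[use])
    }, numeric(1))
    pick <- retained[order(delta, retained)[1]]
    out <- c(out, pick)
    retained <- setdiff(retained, pick)
  }
  out
}

# Brute-force Holdridge classification by scanning all interval boundaries.
oracle_holdridge <- function(bt, ratio) {
  belts <- c(0, 1.5, 3, 6, 12, 24, Inf)
  hums <- c(-Inf, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 32, Inf)
  belt <- NA_integer_
  for (b in seq_len(length(belts) - 1)) {
    if (bt >= belts[b] && bt < belts[b + 1]) belt <- b
  }
  hum <- NA_integer_
  for (h in seq_len(length(hums) - 1)) {
    if (ratio >= hums[h] && ratio < hums[h + 1]) hum <- h
  }
  c(belt = belt, humidity = hum)
}

# Pair-counting adjusted Rand index from two label vectors.
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  npairs <- n * (n - 1) / 2
  expected <- (n11 + n10) * (n11 + n01) / npairs
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(maxi - expected) < 1e-12) return(0)
  (n11 - expected) / (maxi - expected)
}
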