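# Independent oracles kept deliberately naive: they recompute results
# from first principles and must never share code with the implementation.

# Brute-force average-linkage agglomerator: cluster-cluster distances
# are recomputed each step as the plain mean of member pairwise
# distances from the original matrix. Same tie rule as the package
# (near-ties broken by the lexicographically smallest pair of cluster
# creation indices).
brute_force_upgma <- function(d) {
  dm0 <- as.matrix(d)
  n <- nrow(dm0)
  clusters <- as.list(seq_len(n))   # member leaf indices
  code <- -seq_len(n)
  ords <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        avg <- mean(dm0[clusters[[i]], clusters[[j]]])
        if (avg < best_d - 1e-8 * (1 + avg)) {
          best_d <- avg
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(code[i], code[j])
    height[step] <- best_d
    keep <- setdiff(seq_len(k), c(i, j))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    ords <- c(ords[keep], list(c(ords[[i]], ords[[j]])))
    code <- c(code[keep], step)
  }
  list(merge = merge, height = height, order = ords[[1L]])
}

# Two-sided pooled-t p-value straight from the regularized incomplete
# beta function identity, bypassing pt().
p_from_incomplete_beta <- function(t, df) {
  pbeta(df / (df + t^2), df / 2, 1 / 2)
}

# F-distribution upper tail from the incomplete beta identity.
pf_from_incomplete_beta <- function(f, df1, df2) {
  pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}
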