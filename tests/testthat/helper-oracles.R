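# Independent oracles and fixture builders used across the suite.

# Brute-force average-linkage (UPGMA) cophenetic matrix: clusters are kept
# as explicit member lists and every inter-cluster average is recomputed
# from the ORIGINAL distances at every step — no Lance-Williams update, so
# this is an independent route from the package implementation.
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    bestd <- Inf; best <- NULL
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in seq(a + 1L, length(clusters))) {
        avg <- mean(D[clusters[[a]], clusters[[b]]])
        if (avg < bestd) { bestd <- avg; best <- c(a, b) }
      }
    }
    ia <- clusters[[best[1L]]]; ib <- clusters[[best[2L]]]
    coph[ia, ib] <- bestd; coph[ib, ia] <- bestd
    clusters[[best[1L]]] <- c(ia, ib)
    clusters <- clusters[-best[2L]]
  }
  coph
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe where elements 1..K carry the term, and count draws with >= k
# hits.
oracle_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0L) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Hand-executed Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  if (m > 1L) for (i in seq(m - 1L, 1L)) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random symmetric distance matrix with distinct off-diagonal values.
random_dist_matrix <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 2)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# Random ultrametric tree (coalescent) with sorted-friendly labels.
random_ultrametric_tree <- function(n) {
  phy <- ape::rcoal(n, tip.label = sprintf("t%03d", seq_len(n)))
  phy
}

expect_matrix_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a[rownames(b), colnames(b)] - b)), tol)
}
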