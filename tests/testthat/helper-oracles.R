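# Independent brute-force oracles used to check the package's implementations.

# Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# PAC by exhaustive enumeration of off-diagonal pairs.
bf_pac <- function(C, lo = 0.1, hi = 0.9) {
  n <- nrow(C)
  hits <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (C[i, j] > lo && C[i, j] < hi) hits <- hits + 1
  }
  hits / tot
}

# IGP by exhaustive nearest-neighbor enumeration.
bf_igp <- function(V, pred, D, disc) {
  nn <- integer(nrow(V))
  for (i in seq_len(nrow(V))) {
    d <- apply(D, 1, function(r) sum((V[i, ] - r)^2))
    nn[i] <- which.min(d)
  }
  clusters <- sort(unique(c(pred, disc)))
  per <- sapply(clusters, function(cl) {
    sel <- pred == cl
    if (!any(sel)) return(NA_real_)
    mean(disc[nn[sel]] == cl)
  })
  list(per_cluster = per, overall = mean(disc[nn] == pred))
}

# adjusted Rand index between two partitions (mclust is the cross-check
# in the tests that can assume it; this keeps oracles self-contained).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
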