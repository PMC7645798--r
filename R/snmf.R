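#' Sparse non-negative matrix factorization of a burden matrix
#'
#' Factorizes the non-negative patients x mechanisms matrix `X` into
#' `A %*% S` with `A` (patients x k, soft patient-to-cluster assignment) and
#' `S` (k x mechanisms, sparse mechanism-to-cluster loading), minimizing
#' `||X - A S||_F^2 + sparsity * sum(S)` by multiplicative updates. The L1
#' penalty acts on `S` only, sparsifying the mechanism mapping so that each
#' cluster can be read back as a set of driving mechanisms (a bi-clustering).
#' The objective is non-increasing over iterations. Each run's hard label is
#' the per-row argmax of `A` after scale normalization (columns of `A` scaled
#' by the L2 norm of the matching `S` row); ties break to the lowest cluster
#' index.
#'
#' @param X non-negative numeric matrix (patients x mechanisms).
#' @param k number of clusters (1 <= k <= nrow(X)).
#' @param sparsity non-negative L1 weight on `S` (default 0.1).
#' @param seed integer seed for the random uniform initialization.
#' @param max_iter iteration cap (default 500).
#' @param tol relative objective-decrease tolerance (default 1e-6).
#' @return a `factorization_result`: `A`, `S`, `objective`, `trace`,
#'   `iterations`, `labels`, `k`.
#' @export
snmf <- function(X, k, sparsity = 0.1, seed = 1L, max_iter = 500, tol = 1e-6) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite")
  if (any(X < 0)) stop("X must be non-negative")
  n <- nrow(X); m <- ncol(X)
  if (k > n) stop("k must not exceed the number of rows of X")
  if (k < 1) stop("k must be >= 1")
  scale0 <- sqrt(mean(X) / k + 1e-12)
  init <- with_seed(seed, list(
    A = matrix(runif(n * k, 0.05, 1), n, k) * scale0,
    S = matrix(runif(k * m, 0.05, 1), k, m) * scale0))
  fit <- snmf_cpp(X, k, sparsity, tol, max_iter, init$A, init$S)
  rownames(fit$A) <- rownames(X)
  colnames(fit$S) <- colnames(X)
  fit$labels <- snmf_labels(fit$A, fit$S)
  fit$k <- k
  class(fit) <- "factorization_result"
  fit
}

snmf_labels <- function(A, S) {
  d <- sqrt(rowSums(S^2)) + 1e-12
  max.col(sweep(A, 2, d, "*"), ties.method = "first")
}

#' Per-cluster driving mechanisms from the sparse loading matrix
#'
#' Ranks mechanisms by loading within each cluster row of `S` and returns
#' those whose loading reaches `threshold` times the row maximum (default
#' 50%). An all-zero row yields an empty list with a warning.
#'
#' @param S k x mechanisms non-negative loading matrix.
#' @param threshold relative loading threshold in (0, 1\] (default 0.5).
#' @return named list (one per cluster) of ranked mechanism names.
#' @export
top_mechanisms <- function(S, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  mech <- colnames(S) %||% paste0("M", seq_len(ncol(S)))
  out <- lapply(seq_len(nrow(S)), function(r) {
    row <- S[r, ]
    if (all(row == 0)) {
      warning("cluster ", r, " has an all-zero loading row")
      return(character(0))
    }
    keep <- which(row >= threshold * max(row))
    mech[keep[order(row[keep], decreasing = TRUE)]]
  })
  names(out) <- paste0("cluster", seq_len(nrow(S)))
  out
}
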