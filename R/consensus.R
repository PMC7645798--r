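#' Consensus clustering over sNMF restarts and cluster-number selection
#'
#' A single sNMF run depends on the random initialization of both factor
#' matrices, so the factorization is repeated (default 50 times) and the
#' fraction of runs in which two patients share a hard label forms the
#' consensus matrix. Final labels come from average-linkage hierarchical
#' clustering of the consensus distance `1 - C`. Stability of each candidate
#' cluster number is scored by the proportion of ambiguously clustered pairs
#' (PAC), the mean silhouette width, and the cophenetic correlation, and
#' compared with a permutation null in which every burden column is shuffled
#' independently (destroying patient structure while preserving marginals).
#'
#' @name consensus_clustering
NULL

#' Consensus sNMF clustering at a fixed cluster number
#'
#' @param X non-negative patients x mechanisms matrix.
#' @param k number of clusters (>= 2).
#' @param n_runs number of random restarts (default 50, >= 2).
#' @param seed integer seed; restart `r` uses `seed + r`.
#' @param sparsity,max_iter,tol passed to [snmf()].
#' @return a `consensus_result`: consensus matrix `C` (symmetric, unit
#'   diagonal, entries in \[0,1\]), final `labels` (1..k), the `hclust` tree,
#'   `metrics` (PAC, silhouette, cophenetic), and the best-objective
#'   factorization `best_fit`.
#' @export
consensus_cluster <- function(X, k, n_runs = 50, seed = 1L,
                              sparsity = 0.1, max_iter = 500, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (k < 2) stop("k must be >= 2 for consensus clustering")
  C <- matrix(0, n, n)
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- snmf(X, k, sparsity = sparsity, seed = child_seed(seed, r),
                max_iter = max_iter, tol = tol)
    M <- matrix(0, n, k)
    M[cbind(seq_len(n), fit$labels)] <- 1
    C <- C + tcrossprod(M)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  C <- C / n_runs
  diag(C) <- 1
  dimnames(C) <- list(rownames(X), rownames(X))
  hc <- hclust(as.dist(1 - C), method = "average")
  labels <- cutree(hc, k = k)
  metrics <- cluster_metrics(C, labels, hc = hc)
  structure(list(C = C, labels = unname(labels), k = k, n_runs = n_runs,
                 hclust = hc, metrics = metrics, best_fit = best),
            class = "consensus_result")
}

#' Stability metrics of a consensus matrix
#'
#' PAC is the fraction of off-diagonal consensus entries strictly inside
#' (0.1, 0.9); the silhouette is the mean silhouette width on the distance
#' `1 - C` under the given labels (NA, with a warning, when labels form a
#' single cluster); the cophenetic correlation is the Pearson correlation
#' between `1 - C` and the cophenetic distances of the average-linkage tree.
#'
#' @param C consensus matrix.
#' @param labels integer cluster labels.
#' @param hc optional precomputed `hclust` of `as.dist(1 - C)` (average
#'   linkage); recomputed when missing.
#' @param pac_bounds lower/upper ambiguity bounds (default `c(0.1, 0.9)`).
#' @return named list: `pac`, `silhouette`, `cophenetic`.
#' @export
cluster_metrics <- function(C, labels, hc = NULL, pac_bounds = c(0.1, 0.9)) {
  n <- nrow(C)
  off <- C[upper.tri(C)]
  pac <- mean(off > pac_bounds[1] & off < pac_bounds[2])
  d <- as.dist(1 - C)
  if (length(unique(labels)) < 2) {
    warning("silhouette undefined for a single cluster")
    sil <- NA_real_
  } else {
    sil <- mean(cluster::silhouette(labels, dmatrix = as.matrix(d))[, "sil_width"])
  }
  if (is.null(hc)) hc <- hclust(d, method = "average")
  coph <- cophenetic_cpp(hc$merge, hc$height, n)
  coph_cor <- suppressWarnings(cor(as.vector(d), coph))
  list(pac = pac, silhouette = sil, cophenetic = coph_cor)
}

#' Permutation null distribution of the stability metrics
#'
#' Each permutation shuffles every column of `X` independently, then the full
#' consensus clustering and its metrics are recomputed for every candidate k.
#'
#' @param X non-negative patients x mechanisms matrix.
#' @param k_grid integer vector of candidate cluster numbers.
#' @param n_perm number of permutations (>= 20).
#' @param n_runs restarts per consensus run.
#' @param seed integer seed.
#' @param sparsity,max_iter,tol passed to [snmf()].
#' @return named list (one per k) of data frames with columns
#'   `pac`, `silhouette`, `cophenetic` (one row per permutation).
#' @export
permutation_null <- function(X, k_grid, n_perm = 20, n_runs = 50, seed = 1L,
                             sparsity = 0.1, max_iter = 500, tol = 1e-6) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  X <- as.matrix(X)
  out <- lapply(k_grid, function(k)
    data.frame(pac = numeric(n_perm), silhouette = numeric(n_perm),
               cophenetic = numeric(n_perm)))
  names(out) <- as.character(k_grid)
  for (b in seq_len(n_perm)) {
    Xp <- with_seed(child_seed(seed, 50000L + b),
                    apply(X, 2, sample))
    for (ki in seq_along(k_grid)) {
      cc <- consensus_cluster(Xp, k_grid[ki], n_runs = n_runs,
                              seed = child_seed(seed, 1000L * b + k_grid[ki]),
                              sparsity = sparsity, max_iter = max_iter, tol = tol)
      out[[ki]][b, ] <- unlist(cc$metrics)
    }
  }
  out
}

#' Select the number of clusters
#'
#' Among candidate k whose observed silhouette AND cophenetic correlation both
#' exceed the 95th percentile of their permutation null, returns the minimal k
#' attaining the minimum PAC (the most stable solution); if no candidate
#' passes the significance gate, returns `"none"`.
#'
#' @param results named list (per k) of observed metric lists (as returned in
#'   `consensus_result$metrics`).
#' @param nulls named list (per k) of null data frames from
#'   [permutation_null()].
#' @param prob null percentile for the significance gate (default 0.95).
#' @return selected k (integer) or the string `"none"`.
#' @export
select_k <- function(results, nulls, prob = 0.95) {
  ks <- as.integer(names(results))
  if (length(ks) < 2) stop("k grid must contain at least 2 candidates")
  pass <- vapply(seq_along(ks), function(i) {
    obs <- results[[i]]
    nul <- nulls[[as.character(ks[i])]]
    isTRUE(obs$silhouette > quantile(nul$silhouette, prob, na.rm = TRUE)) &&
      isTRUE(obs$cophenetic > quantile(nul$cophenetic, prob, na.rm = TRUE))
  }, logical(1))
  if (!any(pass)) return("none")
  pacs <- vapply(results, function(r) r$pac, numeric(1))
  kp <- ks[pass]
  pp <- pacs[pass]
  min(kp[pp == min(pp)])
}

#' Consensus clustering over a k grid with permutation-calibrated selection
#'
#' Convenience wrapper running [consensus_cluster()] for every candidate k,
#' the column-permutation null, and [select_k()].
#'
#' @inheritParams permutation_null
#' @return list with `per_k` (consensus results), `nulls`, `selected_k`,
#'   and `metrics` (observed metric table).
#' @export
consensus_select_k <- function(X, k_grid = 2:7, n_runs = 50, n_perm = 20,
                               seed = 1L, sparsity = 0.1, max_iter = 500,
                               tol = 1e-6) {
  per_k <- lapply(k_grid, function(k)
    consensus_cluster(X, k, n_runs = n_runs, seed = child_seed(seed, 100L + k),
                      sparsity = sparsity, max_iter = max_iter, tol = tol))
  names(per_k) <- as.character(k_grid)
  nulls <- permutation_null(X, k_grid, n_perm = n_perm, n_runs = n_runs,
                            seed = seed, sparsity = sparsity,
                            max_iter = max_iter, tol = tol)
  results <- lapply(per_k, `[[`, "metrics")
  sel <- select_k(results, nulls)
  metrics <- data.frame(k = k_grid,
                        pac = vapply(results, `[[`, 0, "pac"),
                        silhouette = vapply(results, `[[`, 0, "silhouette"),
                        cophenetic = vapply(results, `[[`, 0, "cophenetic"))
  rownames(metrics) <- NULL
  list(per_k = per_k, nulls = nulls, selected_k = sel, metrics = metrics)
}
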