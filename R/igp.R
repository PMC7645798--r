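#' In-Group Proportion cluster coherence
#'
#' The IGP of a transferred clustering is, per cluster, the fraction of
#' validation-cohort patients assigned to that cluster whose Euclidean nearest
#' neighbor in the discovery cohort carries the same cluster label. An IGP
#' near 1 indicates strong coherence of the validation data with the
#' discovery clustering; near 0, disagreement. Significance comes from a
#' permutation test in which the discovery cluster labels are shuffled and
#' the IGP recomputed (nearest neighbors are label-free and stay fixed).
#'
#' @name igp_validation
NULL

## squared Euclidean cross-distances, nv x nd
cross_dist2 <- function(V, D) {
  outer(rowSums(V^2), rep(1, nrow(D))) +
    outer(rep(1, nrow(V)), rowSums(D^2)) - 2 * tcrossprod(V, D)
}

igp_from_nn <- function(nn_labels, predicted_labels, clusters) {
  per <- vapply(clusters, function(cl) {
    sel <- predicted_labels == cl
    if (!any(sel)) return(NA_real_)
    mean(nn_labels[sel] == cl)
  }, numeric(1))
  overall <- mean(nn_labels == predicted_labels)
  list(per_cluster = per, overall = overall)
}

#' In-Group Proportion of a transferred clustering
#'
#' Both cohorts must live in the same feature space (mechanism burden scores
#' by default in this package). Nearest-neighbor ties break to the lowest
#' discovery patient index. Clusters with no validation patient receive NA
#' with a warning.
#'
#' @param validation_features validation patients x features matrix.
#' @param predicted_labels cluster label per validation patient.
#' @param discovery_features discovery patients x features matrix.
#' @param discovery_labels cluster label per discovery patient.
#' @return an `igp_result`: `per_cluster`, `overall`, `nn_index`.
#' @export
igp <- function(validation_features, predicted_labels,
                discovery_features, discovery_labels) {
  V <- as.matrix(validation_features); D <- as.matrix(discovery_features)
  if (ncol(V) != ncol(D)) stop("feature spaces differ between cohorts")
  stopifnot(length(predicted_labels) == nrow(V),
            length(discovery_labels) == nrow(D))
  d2 <- cross_dist2(V, D)
  nn <- apply(d2, 1, which.min)  # which.min -> lowest index on ties
  clusters <- sort(unique(c(as.character(predicted_labels),
                            as.character(discovery_labels))))
  res <- igp_from_nn(as.character(discovery_labels)[nn],
                     as.character(predicted_labels), clusters)
  if (anyNA(res$per_cluster))
    warning("cluster(s) without validation patients: IGP undefined for ",
            paste(clusters[is.na(res$per_cluster)], collapse = ", "))
  structure(list(per_cluster = setNames(res$per_cluster, clusters),
                 overall = res$overall, nn_index = nn),
            class = "igp_result")
}

#' Permutation test of the In-Group Proportion
#'
#' Shuffles the discovery cluster labels uniformly `n_perm` times (default
#' 1000) and recomputes the IGP; p-values use the add-one estimator
#' `p = (1 + #\{perm IGP >= observed\}) / (n_perm + 1)`, so they are never
#' below `1/(n_perm + 1)`.
#'
#' @inheritParams igp
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return an `igp_result` extended with `p_overall`, `p_per_cluster`,
#'   `n_perm`, and the permutation distribution `null_overall`.
#' @export
igp_permutation_test <- function(validation_features, predicted_labels,
                                 discovery_features, discovery_labels,
                                 n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- igp(validation_features, predicted_labels,
             discovery_features, discovery_labels)
  disc <- as.character(discovery_labels)
  pred <- as.character(predicted_labels)
  clusters <- names(obs$per_cluster)
  null_overall <- numeric(n_perm)
  null_per <- matrix(NA_real_, n_perm, length(clusters),
                     dimnames = list(NULL, clusters))
  with_seed(child_seed(seed, 9L), {
    for (b in seq_len(n_perm)) {
      perm <- sample(disc)
      res <- igp_from_nn(perm[obs$nn_index], pred, clusters)
      null_overall[b] <- res$overall
      null_per[b, ] <- res$per_cluster
    }
  })
  p_overall <- (1 + sum(null_overall >= obs$overall)) / (n_perm + 1)
  p_per <- vapply(clusters, function(cl) {
    if (is.na(obs$per_cluster[cl])) return(NA_real_)
    (1 + sum(null_per[, cl] >= obs$per_cluster[cl], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))
  out <- obs
  out$p_overall <- p_overall
  out$p_per_cluster <- p_per
  out$n_perm <- n_perm
  out$null_overall <- null_overall
  out
}

#' @export
print.igp_result <- function(x, ...) {
  cat("IGP overall:", round(x$overall, 3))
  if (!is.null(x$p_overall)) cat("  (permutation p =", signif(x$p_overall, 3), ")")
  cat("\nper cluster:\n")
  print(round(x$per_cluster, 3))
  invisible(x)
}
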