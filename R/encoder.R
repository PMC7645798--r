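#' Per-mechanism sparse autoencoder burden scores
#'
#' Raw SNP profiles are extremely sparse, which makes distances between
#' patients nearly constant and clustering unstable. Instead, the SNPs mapping
#' to each mechanism are compressed by a small autoencoder with a single
#' bounded bottleneck unit: the bottleneck activation (a sigmoid, hence in
#' \[0,1\]) is the patient's genetic burden score for that mechanism, and the
#' absolute first-layer weights give the relative contribution of each SNP to
#' the score. An L1 penalty on the encoder weights sparsifies the
#' contributions. Bounded scores are simultaneously the non-negativity
#' guarantee required by the downstream NMF.
#'
#' @name burden_encoding
NULL

#' Sparse autoencoder training controls
#'
#' @param bottleneck_dim bottleneck width (only 1 is supported: one burden
#'   score per mechanism).
#' @param sparsity_weight non-negative weight of the L1 penalty on encoder
#'   weights (default 1e-3).
#' @param weight_decay small ridge (L2) term on all weights (default 1e-3);
#'   stabilizes training and resolves the degeneracy of perfectly collinear
#'   SNPs toward the symmetric solution.
#' @param learning_rate Adam step size (default 0.05).
#' @param epochs full-batch epoch cap (default 400).
#' @param tol relative-loss convergence tolerance (default 1e-6).
#' @param seed integer seed for weight initialization.
#' @return an `encoder_spec` list.
#' @export
encoder_spec <- function(bottleneck_dim = 1, sparsity_weight = 1e-3,
                         weight_decay = 1e-3, learning_rate = 0.05,
                         epochs = 400, tol = 1e-6, seed = 1L) {
  if (bottleneck_dim < 1) stop("bottleneck_dim must be >= 1")
  if (bottleneck_dim != 1) stop("only bottleneck_dim = 1 is supported")
  if (sparsity_weight < 0) stop("sparsity_weight must be non-negative")
  structure(list(bottleneck_dim = bottleneck_dim,
                 sparsity_weight = sparsity_weight,
                 weight_decay = weight_decay,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 tol = tol, seed = as.integer(seed)),
            class = "encoder_spec")
}

## per-column mode (for dosage imputation), ignoring NAs
col_modes <- function(X) {
  apply(X, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    tab <- table(x)
    as.numeric(names(tab)[which.max(tab)])
  })
}

impute_mode <- function(X, modes) {
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- modes[j]
  }
  X
}

## full-batch Adam on MSE + lambda * L1(encoder weights) + ridge on w, v
train_ae <- function(Z, lambda, lr, epochs, tol, seed, decay = 0) {
  n <- nrow(Z); p <- ncol(Z)
  with_seed(seed, {
    w <- rnorm(p, 0, 0.1); b <- 0
    v <- rnorm(p, 0, 0.1); cc <- rep(0, p)
    theta <- c(w, b, v, cc)
    m1 <- m2 <- numeric(length(theta))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    g_scale <- 2 / (n * p)
    prev <- Inf; loss <- Inf
    for (epoch in seq_len(epochs)) {
      w <- theta[1:p]; b <- theta[p + 1]
      v <- theta[(p + 2):(2 * p + 1)]; cc <- theta[(2 * p + 2):(3 * p + 1)]
      a <- drop(Z %*% w) + b
      h <- plogis(a)
      E <- tcrossprod(h, v) + matrix(cc, n, p, byrow = TRUE) - Z
      loss <- mean(E^2) + lambda * sum(abs(w)) + decay * (sum(w^2) + sum(v^2))
      gv <- g_scale * drop(crossprod(E, h)) + 2 * decay * v
      gc <- g_scale * colSums(E)
      da <- g_scale * drop(E %*% v) * h * (1 - h)
      gw <- drop(crossprod(Z, da)) + lambda * sign(w) + 2 * decay * w
      gb <- sum(da)
      g <- c(gw, gb, gv, gc)
      m1 <- beta1 * m1 + (1 - beta1) * g
      m2 <- beta2 * m2 + (1 - beta2) * g^2
      theta <- theta - lr * (m1 / (1 - beta1^epoch)) /
        (sqrt(m2 / (1 - beta2^epoch)) + eps)
      if (is.finite(prev) && abs(prev - loss) <= tol * max(1, abs(prev))) break
      prev <- loss
    }
    w <- theta[1:p]; b <- theta[p + 1]
    v <- theta[(p + 2):(2 * p + 1)]; cc <- theta[(2 * p + 2):(3 * p + 1)]
    h <- plogis(drop(Z %*% w) + b)
    mse <- mean((tcrossprod(h, v) + matrix(cc, n, p, byrow = TRUE) - Z)^2)
    list(w = w, b = b, v = v, cc = cc, mse = mse, loss = loss, epochs = epoch)
  })
}

#' Fit the sparse autoencoder of one mechanism
#'
#' Dosages are mode-imputed and standardized per SNP (constant SNPs become
#' zeros); columns are put in canonical (lexicographic) order so the score is
#' invariant to input column order. Training minimizes mean squared
#' reconstruction error plus `sparsity_weight * L1(encoder weights)` by
#' full-batch gradient optimization, deterministic given the seed. If the
#' trained reconstruction does not beat the all-mean baseline, training is
#' retried once from a fresh seed. All-constant input yields a degenerate
#' encoder whose score is the constant 0.5. The score is oriented to correlate
#' non-negatively with total risk-allele dosage, so "higher score" reads as
#' "higher burden".
#'
#' @param dosage_submatrix patients x SNPs dosage matrix of one mechanism.
#' @param spec an [encoder_spec()].
#' @return a `mechanism_encoder` object.
#' @export
fit_mechanism_encoder <- function(dosage_submatrix, spec = encoder_spec()) {
  X <- as.matrix(dosage_submatrix)
  if (ncol(X) < 1) stop("mechanism has no SNP columns")
  ids <- colnames(X)
  if (!is.null(ids)) X <- X[, order(ids), drop = FALSE]
  modes <- col_modes(X)
  X <- impute_mode(X, modes)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  constant <- !is.finite(scale) | scale < 1e-12
  if (all(constant)) {
    enc <- list(w = rep(0, ncol(X)), b = 0, v = rep(0, ncol(X)),
                cc = center, center = center, scale = rep(1, ncol(X)),
                modes = modes, snp_ids = colnames(X), flip = FALSE,
                degenerate = TRUE, mse = 0, baseline_mse = 0, spec = spec)
    class(enc) <- "mechanism_encoder"
    return(enc)
  }
  scl <- ifelse(constant, 1, scale)
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  Z[, constant] <- 0
  baseline <- mean(sweep(Z, 2, colMeans(Z))^2)
  decay <- spec$weight_decay %||% 0
  fit <- train_ae(Z, spec$sparsity_weight, spec$learning_rate,
                  spec$epochs, spec$tol, spec$seed, decay)
  if (fit$mse > baseline) {
    refit <- train_ae(Z, spec$sparsity_weight, spec$learning_rate,
                      spec$epochs, spec$tol, child_seed(spec$seed, 104729L), decay)
    if (refit$mse < fit$mse) fit <- refit
    if (fit$mse > baseline)
      warning("autoencoder did not beat the all-mean baseline after retry")
  }
  h <- plogis(drop(Z %*% fit$w) + fit$b)
  r <- suppressWarnings(cor(h, rowSums(X)))
  flip <- is.finite(r) && r < 0
  enc <- list(w = fit$w, b = fit$b, v = fit$v, cc = fit$cc,
              center = center, scale = scl, modes = modes,
              snp_ids = colnames(X), flip = flip, degenerate = FALSE,
              mse = fit$mse, baseline_mse = baseline, spec = spec)
  class(enc) <- "mechanism_encoder"
  enc
}

#' Score patients with a fitted mechanism encoder
#' @param encoder a `mechanism_encoder`.
#' @param dosage_submatrix patients x SNPs dosage matrix (same SNPs as
#'   training; column order may differ when SNP ids are present).
#' @return numeric burden score vector in \[0,1\].
#' @export
encode_burden <- function(encoder, dosage_submatrix) {
  X <- as.matrix(dosage_submatrix)
  if (nrow(X) == 0) return(numeric(0))
  if (!is.null(encoder$snp_ids) && !is.null(colnames(X))) {
    if (!all(encoder$snp_ids %in% colnames(X)))
      stop("input is missing SNPs the encoder was trained on")
    X <- X[, encoder$snp_ids, drop = FALSE]
  }
  if (ncol(X) != length(encoder$w))
    stop("input width does not match encoder input width")
  if (encoder$degenerate) return(rep(0.5, nrow(X)))
  X <- impute_mode(X, encoder$modes)
  Z <- sweep(sweep(X, 2, encoder$center), 2, encoder$scale, "/")
  h <- plogis(drop(Z %*% encoder$w) + encoder$b)
  if (encoder$flip) h <- 1 - h
  h
}

#' Relative SNP contributions of a fitted encoder
#'
#' `contribution_i = |w_i| / sum_j |w_j|` over the first-layer encoder
#' weights: non-negative and summing to one. A degenerate encoder yields the
#' uniform vector with a warning.
#'
#' @param encoder a `mechanism_encoder`.
#' @return named numeric vector summing to 1.
#' @export
snp_contributions <- function(encoder) {
  p <- length(encoder$w)
  if (encoder$degenerate || sum(abs(encoder$w)) == 0) {
    warning("degenerate encoder: returning uniform contributions")
    return(setNames(rep(1 / p, p), encoder$snp_ids))
  }
  setNames(abs(encoder$w) / sum(abs(encoder$w)), encoder$snp_ids)
}

#' Compute the patients x mechanisms burden profile
#'
#' Trains one sparse autoencoder per mechanism group (seeded as
#' `spec$seed + mechanism index` for reproducibility) and collects the
#' bottleneck scores into a non-negative patients x mechanisms matrix — the
#' input of the consensus sNMF bi-clustering.
#'
#' @param genotypes dosage matrix (or `synthetic_cohort`).
#' @param grouping an `snp_grouping` (named list of SNP id vectors).
#' @param spec an [encoder_spec()].
#' @return a `burden_profile`: `scores` (matrix in \[0,1\]), `contributions`
#'   (per-mechanism normalized weights), `encoders`.
#' @export
compute_burden_scores <- function(genotypes, grouping, spec = encoder_spec()) {
  if (inherits(genotypes, "synthetic_cohort")) genotypes <- genotypes$genotypes
  if (length(grouping) == 0) stop("empty SNP grouping")
  missing <- setdiff(unlist(grouping), colnames(genotypes))
  if (length(missing))
    stop("grouping references SNPs absent from genotypes: ",
         paste(head(missing, 5), collapse = ", "))
  encoders <- vector("list", length(grouping))
  names(encoders) <- names(grouping)
  scores <- matrix(NA_real_, nrow(genotypes), length(grouping),
                   dimnames = list(rownames(genotypes), names(grouping)))
  for (m in seq_along(grouping)) {
    sub <- genotypes[, sort(grouping[[m]]), drop = FALSE]
    sp <- spec; sp$seed <- child_seed(spec$seed, m)
    enc <- fit_mechanism_encoder(sub, sp)
    encoders[[m]] <- enc
    scores[, m] <- encode_burden(enc, sub)
  }
  structure(list(scores = scores,
                 contributions = suppressWarnings(lapply(encoders, snp_contributions)),
                 encoders = encoders),
            class = "burden_profile")
}

#' Score a cohort with already-fitted encoders
#'
#' Projects new patients into the discovery-trained burden space without
#' retraining — used to place validation-cohort patients into the feature
#' space the discovery clustering was built in.
#'
#' @param encoders a `burden_profile` or its `encoders` list.
#' @param genotypes dosage matrix (or `synthetic_cohort`) containing every
#'   SNP the encoders were trained on.
#' @return a `burden_profile` (without refitted encoders).
#' @export
apply_encoders <- function(encoders, genotypes) {
  if (inherits(encoders, "burden_profile")) encoders <- encoders$encoders
  if (inherits(genotypes, "synthetic_cohort")) genotypes <- genotypes$genotypes
  scores <- matrix(NA_real_, nrow(genotypes), length(encoders),
                   dimnames = list(rownames(genotypes), names(encoders)))
  for (m in seq_along(encoders)) {
    enc <- encoders[[m]]
    sub <- genotypes[, enc$snp_ids, drop = FALSE]
    scores[, m] <- encode_burden(enc, sub)
  }
  structure(list(scores = scores,
                 contributions = suppressWarnings(lapply(encoders, snp_contributions)),
                 encoders = encoders),
            class = "burden_profile")
}

#' Serialize fitted encoders to a JSON weight file
#' @param profile a `burden_profile`.
#' @param path output `.json` file.
#' @export
write_encoders_json <- function(profile, path) {
  encs <- lapply(profile$encoders, function(e)
    e[c("w", "b", "v", "cc", "center", "scale", "modes", "snp_ids",
        "flip", "degenerate", "mse", "baseline_mse")])
  jsonlite::write_json(encs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoders_json
#' @export
read_encoders_json <- function(path) {
  encs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(encs, function(e) {
    e[c("w", "v", "cc", "center", "scale", "modes")] <-
      lapply(e[c("w", "v", "cc", "center", "scale", "modes")], as.numeric)
    e$snp_ids <- as.character(e$snp_ids)
    class(e) <- "mechanism_encoder"
    e
  })
}

#' Write a burden profile as TSV (patients x mechanisms)
#' @param profile a `burden_profile`.
#' @param path output file.
#' @export
write_burden_tsv <- function(profile, path) {
  df <- data.frame(patient_id = rownames(profile$scores), profile$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
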