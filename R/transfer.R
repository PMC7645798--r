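#' Cluster transfer to independent cohorts via penalized multinomial regression
#'
#' Discovery-cohort cluster labels are learned by an L1-penalized (LASSO)
#' multinomial logistic classifier so that patients of an independent
#' validation cohort can be assigned to the discovered clusters. Prediction
#' performance is estimated by repeated stratified ten-fold cross-validation
#' with the Hand-Till one-vs-one average multi-class AUC; when the feature
#' space is the mechanism burden profile, the autoencoders are refit inside
#' every training fold so the reported AUC carries no information leak.
#'
#' @name transfer_validation
NULL

#' Fit the L1-penalized multinomial transfer classifier
#'
#' The penalty strength is chosen by cross-validated multinomial deviance over
#' a 30-point log-spaced grid anchored at glmnet's max-gradient lambda.
#'
#' @param features numeric matrix (patients x features): burden scores
#'   (default feature space) or raw SNP dosages.
#' @param labels cluster labels (>= 2 classes, each with >= 2 members).
#' @param lambda_grid optional decreasing lambda grid; a single value skips
#'   the inner cross-validation.
#' @param seed integer seed (controls the CV fold assignment).
#' @param nfolds inner CV folds for lambda selection (default 5).
#' @param feature_space tag recorded on the model: `"burden"` or `"snp"`.
#' @return a `transfer_model`: glmnet fit, chosen `lambda`, coefficient
#'   matrix, class levels, feature space tag.
#' @export
fit_transfer_classifier <- function(features, labels, lambda_grid = NULL,
                                    seed = 1L, nfolds = 5,
                                    feature_space = "burden") {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 members")
  if (is.null(lambda_grid)) {
    path <- glmnet::glmnet(features, labels, family = "multinomial")
    lmax <- max(path$lambda)
    lambda_grid <- sort(lmax * 10^seq(-4, 2, length.out = 30), decreasing = TRUE)
  }
  if (length(lambda_grid) == 1) {
    fit <- glmnet::glmnet(features, labels, family = "multinomial",
                          lambda = lambda_grid)
    lambda <- lambda_grid
    cvm <- NA_real_
  } else {
    foldid <- with_seed(seed, stratified_folds(labels, nfolds))
    cv <- glmnet::cv.glmnet(features, labels, family = "multinomial",
                            lambda = sort(lambda_grid, decreasing = TRUE),
                            foldid = foldid, type.measure = "deviance")
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
    cvm <- min(cv$cvm)
  }
  cf <- coef(fit, s = lambda)
  coefs <- do.call(cbind, lapply(cf, function(m) as.matrix(m)[, 1]))
  colnames(coefs) <- names(cf)
  structure(list(fit = fit, lambda = lambda, coefficients = t(coefs),
                 classes = levels(labels), feature_space = feature_space,
                 cv_deviance = cvm),
            class = "transfer_model")
}

## stratified fold ids 1..folds, balanced within each class
stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' Assign patients to discovery clusters
#'
#' @param model a `transfer_model`.
#' @param validation_features feature matrix with the training feature width.
#' @return list with `labels` (predicted cluster per patient) and
#'   `probabilities` (rows sum to 1).
#' @export
assign_clusters <- function(model, validation_features) {
  validation_features <- as.matrix(validation_features)
  if (ncol(validation_features) != ncol(model$coefficients) - 1L)
    stop("feature width does not match the trained model")
  probs <- predict(model$fit, newx = validation_features, s = model$lambda,
                   type = "response")[, , 1]
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, model$classes))
  labels <- model$classes[max.col(probs, ties.method = "first")]
  list(labels = labels, probabilities = probs)
}

## rank-based binary AUC of `scores` discriminating pos (TRUE) from neg
auc_rank <- function(scores, pos) {
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hand-Till multi-class AUC
#'
#' Average over all unordered class pairs (i, j) of
#' `(A(i|j) + A(j|i)) / 2`, where `A(i|j)` is the rank AUC of the class-i
#' probability separating class i from class j.
#'
#' @param probabilities patients x classes probability matrix (column names =
#'   class labels).
#' @param labels true class per patient.
#' @return scalar AUC in \[0,1\].
#' @export
hand_till_auc <- function(probabilities, labels) {
  labels <- as.character(labels)
  classes <- colnames(probabilities)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  vals <- vapply(pairs, function(pr) {
    sel <- labels %in% pr
    pos_i <- labels[sel] == pr[1]
    a_ij <- auc_rank(probabilities[sel, pr[1]], pos_i)
    a_ji <- auc_rank(probabilities[sel, pr[2]], !pos_i)
    (a_ij + a_ji) / 2
  }, numeric(1))
  mean(vals)
}

#' Repeated stratified cross-validated multi-class AUC
#'
#' `repeats` x `folds` stratified cross-validation of the transfer
#' classifier. When `genotypes` and `grouping` are supplied (burden feature
#' space), the per-mechanism autoencoders are refit on each training fold and
#' applied to the held-out fold, so burden encoding happens inside the CV
#' loop; otherwise `features` is used as-is. The AUC of each repeat is the
#' Hand-Till statistic on the pooled out-of-fold class probabilities.
#'
#' @param features feature matrix (ignored when `genotypes` is given).
#' @param labels cluster labels; every class must have >= `folds` members.
#' @param repeats,folds repetition and fold counts (defaults 10 and 10).
#' @param seed integer seed.
#' @param genotypes optional dosage matrix for in-loop burden encoding.
#' @param grouping optional `snp_grouping` (required with `genotypes`).
#' @param spec [encoder_spec()] for in-loop encoding.
#' @param nfolds inner folds for lambda selection (default 5).
#' @return list with `auc` (mean over repeats) and `per_repeat`.
#' @export
cross_validate <- function(features, labels, repeats = 10, folds = 10,
                           seed = 1L, genotypes = NULL, grouping = NULL,
                           spec = encoder_spec(), nfolds = 5) {
  labels <- factor(labels)
  if (any(table(labels) < folds))
    stop("every class needs at least `folds` members for stratified folding")
  in_loop <- !is.null(genotypes)
  if (in_loop && is.null(grouping)) stop("grouping required with genotypes")
  if (in_loop && inherits(genotypes, "synthetic_cohort"))
    genotypes <- genotypes$genotypes
  n <- length(labels)
  per_repeat <- numeric(repeats)
  for (rep_i in seq_len(repeats)) {
    foldid <- with_seed(child_seed(seed, rep_i), stratified_folds(labels, folds))
    probs <- matrix(NA_real_, n, nlevels(labels),
                    dimnames = list(NULL, levels(labels)))
    for (f in seq_len(folds)) {
      test <- foldid == f
      if (in_loop) {
        sp <- spec; sp$seed <- child_seed(spec$seed, 1000L * rep_i + f)
        prof <- compute_burden_scores(genotypes[!test, , drop = FALSE],
                                      grouping, sp)
        xtr <- prof$scores
        xte <- apply_encoders(prof, genotypes[test, , drop = FALSE])$scores
      } else {
        xtr <- as.matrix(features)[!test, , drop = FALSE]
        xte <- as.matrix(features)[test, , drop = FALSE]
      }
      model <- fit_transfer_classifier(xtr, labels[!test],
                                       seed = child_seed(seed, 7000L + rep_i * folds + f),
                                       nfolds = nfolds)
      probs[test, ] <- assign_clusters(model, xte)$probabilities[, levels(labels)]
    }
    per_repeat[rep_i] <- hand_till_auc(probs, labels)
  }
  list(auc = mean(per_repeat), per_repeat = per_repeat)
}
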