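#' Cluster-phenotype association statistics
#'
#' Clusters are tested against clinical, CSF or imaging-derived outcomes with
#' multinomial logistic models (cluster indicator as response, so skewed
#' outcome distributions need no distributional assumption), confounder
#' control via stepwise AIC selection, likelihood-ratio tests for each
#' outcome, post-hoc pairwise Wald tests between clusters, joint
#' Benjamini-Hochberg correction, and random-intercept mixed models for
#' longitudinal progression scores.
#'
#' @name association_stats
NULL

#' Stepwise AIC selection of confounders
#'
#' Bidirectional stepwise search (starting from the null model) over candidate
#' confounders with the multinomial logistic likelihood of the cluster
#' indicator, using the AIC. Candidates that (quasi-)separate the clusters —
#' near-zero residual deviance or exploding coefficients in a univariate fit —
#' are skipped with a warning, as are candidates whose univariate fit fails.
#'
#' @param labels cluster labels (>= 2 clusters).
#' @param candidates data frame of candidate confounders (columns = terms).
#' @return a `confounder_selection`: `candidates`, `selected`, `aic_trace`
#'   (the stepwise path), `aic_null`, `aic_final`.
#' @export
select_confounders <- function(labels, candidates) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 clusters")
  stopifnot(is.data.frame(candidates), nrow(candidates) == length(labels))
  usable <- character(0)
  for (nm in names(candidates)) {
    df1 <- data.frame(.cluster = labels, x = candidates[[nm]])
    fit <- tryCatch(
      nnet::multinom(.cluster ~ x, data = df1, trace = FALSE, maxit = 200),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("candidate '", nm, "' failed to fit; skipped")
      next
    }
    if (fit$deviance < 1e-6 || max(abs(coef(fit))) > 20) {
      warning("candidate '", nm, "' (quasi-)separates the clusters; skipped")
      next
    }
    usable <- c(usable, nm)
  }
  df <- data.frame(.cluster = labels, candidates[usable], check.names = FALSE)
  null <- nnet::multinom(.cluster ~ 1, data = df, trace = FALSE, maxit = 500)
  if (length(usable) == 0) {
    return(structure(list(candidates = names(candidates), selected = character(0),
                          aic_trace = NULL, aic_null = AIC(null),
                          aic_final = AIC(null)),
                     class = "confounder_selection"))
  }
  upper <- reformulate(sprintf("`%s`", usable), response = ".cluster")
  step_fit <- MASS::stepAIC(null, scope = list(lower = ~1, upper = upper),
                            direction = "both", trace = 0)
  selected <- attr(terms(step_fit), "term.labels")
  selected <- gsub("`", "", selected)
  structure(list(candidates = names(candidates), selected = selected,
                 aic_trace = step_fit$anova, aic_null = AIC(null),
                 aic_final = AIC(step_fit)),
            class = "confounder_selection")
}

wald_pairwise <- function(fit, term, levels_) {
  cf <- coef(fit)
  V <- vcov(fit)
  if (is.null(dim(cf))) {
    # binary case: coef is a vector and vcov rows carry no class prefix
    cf <- matrix(cf, nrow = 1, dimnames = list(levels_[2], names(cf)))
    nm <- term
  } else {
    nm <- paste0(rownames(cf), ":", term)
  }
  b <- setNames(cf[, term], rownames(cf))
  k <- length(levels_)
  out <- list()
  for (a in 1:(k - 1)) for (d in (a + 1):k) {
    la <- levels_[a]; ld <- levels_[d]
    if (a == 1) {           # baseline vs d
      est <- b[[ld]]
      se <- sqrt(V[nm[match(ld, rownames(cf))], nm[match(ld, rownames(cf))]])
    } else {
      ia <- nm[match(la, rownames(cf))]; id <- nm[match(ld, rownames(cf))]
      est <- b[[ld]] - b[[la]]
      se <- sqrt(V[ia, ia] + V[id, id] - 2 * V[ia, id])
    }
    z <- est / se
    out[[length(out) + 1L]] <- data.frame(
      cluster_a = la, cluster_b = ld, estimate = est, se = se, z = z,
      p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Test one outcome for association with the clusters
#'
#' Fits the multinomial logistic model `cluster ~ confounders + outcome` and
#' compares it against `cluster ~ confounders` with a likelihood-ratio test
#' (analysis of deviance / single-term-deletion type III test, df = k - 1).
#' On nominal significance (raw LRT p < `pairwise_alpha`), post-hoc pairwise
#' Wald tests on the outcome coefficient are computed for every cluster pair.
#' P-values are raw; joint BH correction across a whole battery of tests is
#' applied afterwards with [adjust_bh()].
#'
#' @param outcome numeric (or ordinal-coded) outcome vector.
#' @param labels cluster labels; every cluster needs >= 5 members.
#' @param confounders optional data frame of selected confounders.
#' @param outcome_name label used in the result.
#' @param pairwise_alpha nominal gate for the post-hoc tests (default 0.05).
#' @return an `association_result`: `outcome`, `lrt_stat`, `df`, `p`,
#'   `pairwise` (data frame or NULL), `aic`, `converged`.
#' @export
outcome_association <- function(outcome, labels, confounders = NULL,
                                outcome_name = deparse(substitute(outcome)),
                                pairwise_alpha = 0.05) {
  labels <- factor(labels)
  keep <- !is.na(outcome)
  if (!is.null(confounders)) keep <- keep & complete.cases(confounders)
  outcome <- outcome[keep]; labels <- droplevels(labels[keep])
  if (any(table(labels) < 5)) stop("every cluster needs >= 5 patients")
  df <- data.frame(.cluster = labels, .outcome = outcome)
  rhs0 <- "1"
  if (!is.null(confounders) && ncol(confounders) > 0) {
    df <- cbind(df, confounders[keep, , drop = FALSE])
    rhs0 <- paste(sprintf("`%s`", names(confounders)), collapse = " + ")
  }
  f0 <- as.formula(paste(".cluster ~", rhs0))
  f1 <- as.formula(paste(".cluster ~", rhs0, "+ .outcome"))
  fit0 <- nnet::multinom(f0, data = df, trace = FALSE, maxit = 1000,
                         abstol = 1e-12, reltol = 1e-12)
  fit1 <- nnet::multinom(f1, data = df, trace = FALSE, maxit = 1000,
                         abstol = 1e-12, reltol = 1e-12)
  converged <- fit1$convergence == 0 && fit0$convergence == 0
  stat <- fit0$deviance - fit1$deviance
  dfree <- nlevels(labels) - 1
  p <- pchisq(stat, dfree, lower.tail = FALSE)
  pairwise <- NULL
  if (converged && is.finite(p) && p < pairwise_alpha) {
    pairwise <- wald_pairwise(fit1, ".outcome", levels(labels))
  }
  if (!converged)
    warning("multinomial fit for '", outcome_name,
            "' did not converge; exclude it from the BH family")
  structure(list(outcome = outcome_name, lrt_stat = stat, df = dfree, p = p,
                 pairwise = pairwise, aic = AIC(fit1), converged = converged),
            class = "association_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Joint FDR correction of all raw p-values of one study battery (LRT and
#' pairwise Wald p-values pooled). Adjusted values are monotone in the raw
#' values and never below them.
#'
#' @param p_values numeric vector in \[0,1\]; NA/NaN is an error.
#' @return adjusted p-values (same order as the input).
#' @export
adjust_bh <- function(p_values) {
  if (anyNA(p_values)) stop("p_values must not contain NA/NaN")
  if (any(p_values < 0 | p_values > 1)) stop("p_values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Longitudinal progression model between two clusters
#'
#' For every visit the progression score is the outcome minus its baseline
#' value, divided by the standard deviation of the baseline values (so the
#' baseline visit scores exactly 0 and progression is in baseline-SD units).
#' A linear mixed model with fixed cluster, time and cluster x time effects
#' and a per-patient random intercept is fit by maximum likelihood to the
#' follow-up visits (the baseline progression score is identically zero and
#' carries no information); time is
#' coded numerically or categorically, whichever yields the lower AIC. The
#' cluster effect (main + interaction jointly) is tested by a likelihood-ratio
#' test against the time-only model; the interaction alone against the
#' additive model. A singular random-effect fit falls back to the
#' fixed-effects linear model with a warning.
#'
#' @param visit_table data frame with columns `patient_id`, `cluster`,
#'   `visit`, `value` (as returned by [generate_longitudinal()]).
#' @param cluster_pair optional length-2 vector restricting the comparison to
#'   two clusters (default: all clusters present).
#' @return a `progression_result`: `time_coding`, `aic` (both codings),
#'   `ri_variance`, `p_cluster`, `p_interaction`, `fixed_effects`, `model`,
#'   `fallback_lm`.
#' @export
longitudinal_association <- function(visit_table, cluster_pair = NULL) {
  vt <- visit_table
  stopifnot(all(c("patient_id", "cluster", "visit", "value") %in% names(vt)))
  if (!is.null(cluster_pair)) vt <- vt[vt$cluster %in% cluster_pair, , drop = FALSE]
  if (length(unique(vt$cluster)) < 2) stop("both clusters must be represented")
  nv <- tapply(vt$visit, vt$patient_id, function(v) length(unique(v)))
  if (any(nv < 2)) stop("every patient needs >= 2 visits")
  b0 <- vt$visit == min(vt$visit)
  base <- vt[b0, ]
  sd0 <- sd(base$value)
  if (!is.finite(sd0) || sd0 == 0) stop("baseline outcome has zero variance")
  vt$prog <- (vt$value - base$value[match(vt$patient_id, base$patient_id)]) / sd0
  vt <- vt[!b0, , drop = FALSE]  # baseline rows are identically zero
  vt$.cluster <- factor(vt$cluster)
  if (length(unique(vt$visit)) == 1) {
    # a single follow-up visit: no time axis, plain between-cluster comparison
    warning("single follow-up visit; fitting the cluster contrast without time")
    fit <- stats::lm(prog ~ .cluster, data = vt)
    p_cluster <- anova(stats::lm(prog ~ 1, data = vt), fit)[2, "Pr(>F)"]
    return(structure(list(cluster_pair = sort(unique(as.character(vt$cluster))),
                          time_coding = "none", aic = c(AIC(fit)),
                          ri_variance = 0, p_cluster = p_cluster,
                          p_interaction = NA_real_, fixed_effects = coef(fit),
                          model = fit, fallback_lm = TRUE, baseline_sd = sd0),
                     class = "progression_result"))
  }
  fits <- lapply(c(numeric = FALSE, categorical = TRUE), function(cat_time) {
    vt$.time <- if (cat_time) factor(vt$visit) else vt$visit
    suppressMessages(tryCatch(
      lme4::lmer(prog ~ .cluster * .time + (1 | patient_id), data = vt,
                 REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL))
  })
  aics <- vapply(fits, function(f) if (is.null(f)) Inf else AIC(f), numeric(1))
  coding <- names(which.min(aics))
  fit <- fits[[coding]]
  vt$.time <- if (coding == "categorical") factor(vt$visit) else vt$visit
  fallback <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (fallback) {
    warning("singular random-intercept fit; falling back to fixed-effects model")
    fit <- stats::lm(prog ~ .cluster * .time, data = vt)
    null_t <- stats::lm(prog ~ .time, data = vt)
    add <- stats::lm(prog ~ .cluster + .time, data = vt)
    p_cluster <- anova(null_t, fit)[2, "Pr(>F)"]
    p_inter <- anova(add, fit)[2, "Pr(>F)"]
    ri_var <- 0
    fe <- coef(fit)
  } else {
    null_t <- update(fit, . ~ .time + (1 | patient_id))
    add <- update(fit, . ~ .cluster + .time + (1 | patient_id))
    p_cluster <- anova(null_t, fit)[2, "Pr(>Chisq)"]
    p_inter <- anova(add, fit)[2, "Pr(>Chisq)"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_var <- vc$vcov[vc$grp == "patient_id"]
    fe <- lme4::fixef(fit)
  }
  structure(list(cluster_pair = sort(unique(as.character(vt$cluster))),
                 time_coding = coding, aic = aics, ri_variance = ri_var,
                 p_cluster = p_cluster, p_interaction = p_inter,
                 fixed_effects = fe, model = fit, fallback_lm = fallback,
                 baseline_sd = sd0),
            class = "progression_result")
}

#' Run a battery of baseline outcome tests with joint BH correction
#'
#' Convenience wrapper: selects confounders once, tests each outcome, pools
#' every LRT and pairwise Wald p-value of the battery and adjusts them
#' jointly by BH, writing adjusted values back onto the results.
#'
#' @param outcomes data frame of outcome columns.
#' @param labels cluster labels.
#' @param candidates optional data frame of candidate confounders.
#' @param fixed_confounders optional character vector forcing a fixed
#'   confounder set (e.g. `c("age", "sex")` for imaging-derived outcomes),
#'   bypassing stepwise selection.
#' @return list with `selection`, `results` (per outcome), and `table` (tidy
#'   one-row-per-test data frame with `p_adjusted`).
#' @export
association_battery <- function(outcomes, labels, candidates = NULL,
                                fixed_confounders = NULL) {
  selection <- NULL
  conf <- NULL
  if (!is.null(fixed_confounders)) {
    conf <- candidates[, fixed_confounders, drop = FALSE]
  } else if (!is.null(candidates) && ncol(candidates) > 0) {
    selection <- select_confounders(labels, candidates)
    if (length(selection$selected))
      conf <- candidates[, selection$selected, drop = FALSE]
  }
  results <- lapply(names(outcomes), function(nm)
    outcome_association(outcomes[[nm]], labels, conf, outcome_name = nm))
  names(results) <- names(outcomes)
  rows <- list()
  for (r in results) {
    if (!r$converged) next
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = r$outcome, test = "LRT", cluster_a = NA, cluster_b = NA,
      statistic = r$lrt_stat, p = r$p, stringsAsFactors = FALSE)
    if (!is.null(r$pairwise)) {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = r$outcome, test = "Wald",
        cluster_a = r$pairwise$cluster_a, cluster_b = r$pairwise$cluster_b,
        statistic = r$pairwise$z, p = r$pairwise$p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) tab$p_adjusted <- adjust_bh(tab$p)
  list(selection = selection, results = results, table = tab)
}
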