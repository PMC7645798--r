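#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the generative design for a synthetic AD/PD genotype
#' cohort with planted mechanism-structured cluster signal. Defaults emulate
#' the statistical shape of the study the package targets: a discovery cohort
#' of 486 AD + 358 PD patients genotyped at 148 SNPs grouped into 15
#' mechanisms over 27 genes, a validation cohort of 561 patients drawn from
#' the same generative law, 4 planted clusters burdening cyclic mechanism
#' mixtures, and confounders (age, sex, study) drawn independently of cluster.
#'
#' Dosages are Hardy-Weinberg binomial draws: SNP `j` of a patient in cluster
#' `c` is `Binomial(2, f_j + delta * signature[c, mech(j)])` where `f_j` is the
#' baseline minor-allele frequency. `effect_delta` is therefore an absolute
#' allele-frequency shift; the planted mean dosage difference between burdened
#' and non-burdened clusters is `2 * effect_delta` per SNP.
#'
#' @param n_patients_ad,n_patients_pd discovery cohort sizes (default 486/358).
#' @param n_validation validation cohort size (default 561).
#' @param k_true number of planted clusters (default 4).
#' @param group_sizes SNP count per mechanism; must all be >= 1. The default
#'   (sum 148) mirrors the packaged catalogue's per-mechanism SNP counts.
#' @param maf_range interval for baseline minor-allele frequencies.
#' @param effect_delta allele-frequency shift applied to signature SNPs;
#'   all shifted frequencies must stay inside (0, 1).
#' @param signature binary `k_true` x n_mechanisms matrix; default is the
#'   cyclic design in which cluster `c` burdens mechanisms `c, c+k, c+2k, ...`
#'   so every cluster is a mixture of mechanisms.
#' @param cluster_proportions simplex vector of length `k_true`.
#' @param confounder_spec list with `age_mean_ad`, `age_sd_ad`, `age_mean_pd`,
#'   `age_sd_pd` (years) and `p_male`.
#' @param outcome_spec named list of outcomes, each with `cluster_means`
#'   (length `k_true`, SD units), `sd`, `beta_age` (per year), `beta_sex`.
#' @param longitudinal_spec list with per-cluster `slopes` (SD units/visit),
#'   `ri_sd` (patient random-intercept SD), `noise_sd`.
#' @param n_visits number of visits for longitudinal outcomes (>= 2).
#' @param miss_rate missing-completely-at-random dosage fraction (default 0).
#' @param val_ad_fraction fraction of AD patients in the validation cohort
#'   (default 258/561, the emulated ROSMAP+IDIBAPS vs PD-study split).
#' @param snp_ids optional SNP id vector (length `sum(group_sizes)`).
#' @param seed integer master seed; all random streams derive from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients_ad = 486,
                             n_patients_pd = 358,
                             n_validation = 561,
                             k_true = 4,
                             group_sizes = default_group_sizes(),
                             maf_range = c(0.05, 0.45),
                             effect_delta = 0.2,
                             signature = NULL,
                             cluster_proportions = rep(1 / k_true, k_true),
                             confounder_spec = list(age_mean_ad = 73, age_sd_ad = 8,
                                                    age_mean_pd = 62, age_sd_pd = 10,
                                                    p_male = 0.55),
                             outcome_spec = list(
                               severity = list(cluster_means = seq(0, by = 0.5, length.out = k_true),
                                               sd = 1, beta_age = 0.02, beta_sex = 0.2),
                               null_score = list(cluster_means = rep(0, k_true),
                                                 sd = 1, beta_age = 0, beta_sex = 0)),
                             longitudinal_spec = list(
                               slopes = seq(0, by = 0.25, length.out = k_true),
                               ri_sd = 0.3, noise_sd = 0.5),
                             n_visits = 4,
                             miss_rate = 0,
                             val_ad_fraction = 258 / 561,
                             snp_ids = NULL,
                             seed = 1234) {
  n_mech <- length(group_sizes)
  if (is.null(signature)) signature <- cyclic_signature(k_true, n_mech)
  cfg <- list(n_patients_ad = n_patients_ad, n_patients_pd = n_patients_pd,
              n_validation = n_validation, k_true = k_true,
              group_sizes = group_sizes, maf_range = maf_range,
              effect_delta = effect_delta, signature = signature,
              cluster_proportions = cluster_proportions,
              confounder_spec = confounder_spec, outcome_spec = outcome_spec,
              longitudinal_spec = longitudinal_spec, n_visits = n_visits,
              miss_rate = miss_rate, val_ad_fraction = val_ad_fraction,
              snp_ids = snp_ids, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default per-mechanism SNP counts (sum 148, matching the packaged catalogue)
#' @return integer vector of length 15.
#' @export
default_group_sizes <- function() {
  stats::setNames(
    c(8L, 18L, 6L, 6L, 15L, 8L, 7L, 11L, 9L, 5L, 4L, 10L, 15L, 14L, 12L),
    c("M01_AKT_signaling", "M02_inflammasome", "M03_homocysteine_ox",
      "M04_JNK_signaling", "M05_lipoprotein_APOE", "M06_tau_microtubule",
      "M07_synuclein_agg", "M08_kinase_GSK_CDK", "M09_endocytosis_immune",
      "M10_IL6_signaling", "M11_apoptosis_cytc", "M12_synthetic_a",
      "M13_synthetic_b", "M14_synthetic_c", "M15_synthetic_d"))
}

#' Cyclic cluster-to-mechanism burden signature
#'
#' Cluster `c` burdens mechanisms `c, c+k, c+2k, ...`, so each planted cluster
#' is a mixture of several mechanisms rather than an instance of a single one.
#'
#' @param k number of clusters; @param n_mech number of mechanisms.
#' @return binary `k` x `n_mech` matrix.
#' @export
cyclic_signature <- function(k, n_mech) {
  sig <- matrix(0L, k, n_mech)
  for (m in seq_len(n_mech)) sig[((m - 1L) %% k) + 1L, m] <- 1L
  sig
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$group_sizes < 1)) stop("configuration error: group_sizes must all be >= 1")
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-8 || any(cfg$cluster_proportions < 0))
    stop("configuration error: cluster_proportions must be a simplex vector")
  if (length(cfg$cluster_proportions) != cfg$k_true)
    stop("configuration error: cluster_proportions length must equal k_true")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) || any(cfg$maf_range >= 1) ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("configuration error: maf_range must be an increasing interval inside (0,1)")
  if (cfg$effect_delta < 0 || cfg$maf_range[2] + cfg$effect_delta >= 1)
    stop("configuration error: effect_delta pushes allele frequencies outside (0,1)")
  if (!is.matrix(cfg$signature) || nrow(cfg$signature) != cfg$k_true ||
      ncol(cfg$signature) != length(cfg$group_sizes))
    stop("configuration error: signature must be k_true x n_mechanisms")
  if (!is.null(cfg$snp_ids) && length(cfg$snp_ids) != sum(cfg$group_sizes))
    stop("configuration error: snp_ids length must equal sum(group_sizes)")
  for (nm in names(cfg$outcome_spec)) {
    if (length(cfg$outcome_spec[[nm]]$cluster_means) != cfg$k_true)
      stop("configuration error: outcome '", nm, "' cluster_means length != k_true")
  }
  if (cfg$miss_rate < 0 || cfg$miss_rate >= 1)
    stop("configuration error: miss_rate must be in [0,1)")
  invisible(cfg)
}

config_snp_ids <- function(cfg) {
  if (!is.null(cfg$snp_ids)) return(cfg$snp_ids)
  sprintf("snp%03d", seq_len(sum(cfg$group_sizes)))
}

config_mechanism_of_snp <- function(cfg) {
  rep(seq_along(cfg$group_sizes), cfg$group_sizes)
}

draw_mafs <- function(cfg) {
  with_seed(child_seed(cfg$seed, 1L),
            runif(sum(cfg$group_sizes), cfg$maf_range[1], cfg$maf_range[2]))
}

simulate_patients <- function(cfg, n, n_ad, id_prefix, stream) {
  mafs <- draw_mafs(cfg)
  p <- sum(cfg$group_sizes)
  mech_of <- config_mechanism_of_snp(cfg)
  with_seed(child_seed(cfg$seed, stream), {
    clusters <- sample.int(cfg$k_true, n, replace = TRUE,
                           prob = cfg$cluster_proportions)
    freq <- matrix(mafs, n, p, byrow = TRUE) +
      cfg$effect_delta * cfg$signature[clusters, mech_of, drop = FALSE]
    dos <- matrix(rbinom(n * p, 2L, freq), n, p)
    if (cfg$miss_rate > 0) dos[runif(n * p) < cfg$miss_rate] <- NA_integer_
    disease <- rep(c("AD", "PD"), c(n_ad, n - n_ad))
    cs <- cfg$confounder_spec
    age <- ifelse(disease == "AD",
                  rnorm(n, cs$age_mean_ad, cs$age_sd_ad),
                  rnorm(n, cs$age_mean_pd, cs$age_sd_pd))
    sex <- rbinom(n, 1L, cs$p_male)
    outcomes <- lapply(cfg$outcome_spec, function(o)
      o$cluster_means[clusters] + o$beta_age * (age - mean(age)) +
        o$beta_sex * sex + rnorm(n, 0, o$sd))
    list(clusters = clusters, dosages = dos, disease = disease,
         age = age, sex = sex, outcomes = outcomes)
  })
}

build_cohort <- function(cfg, sim, id_prefix, study) {
  n <- length(sim$clusters)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  geno <- sim$dosages
  dimnames(geno) <- list(ids, config_snp_ids(cfg))
  covariates <- data.frame(patient_id = ids, age = sim$age,
                           sex = factor(sim$sex, levels = 0:1,
                                        labels = c("F", "M")),
                           disease = sim$disease, study = study,
                           stringsAsFactors = FALSE)
  outcomes <- data.frame(patient_id = ids, sim$outcomes,
                         stringsAsFactors = FALSE)
  mech_names <- names(cfg$group_sizes) %||%
    sprintf("M%02d", seq_along(cfg$group_sizes))
  grouping <- structure(split(config_snp_ids(cfg),
                              config_mechanism_of_snp(cfg)),
                        names = mech_names, class = "snp_grouping")
  structure(list(genotypes = geno,
                 true_labels = sim$clusters,
                 covariates = covariates,
                 outcomes = outcomes,
                 grouping = grouping,
                 config = cfg),
            class = "synthetic_cohort")
}

#' Generate a synthetic discovery cohort
#'
#' Draws `n_patients_ad + n_patients_pd` patients: a planted cluster per
#' patient from `cluster_proportions`, Hardy-Weinberg binomial dosages with
#' mechanism-specific allele-frequency enrichment (`effect_delta`) for the
#' patient's cluster signature, confounders independent of cluster, and
#' cluster-linked baseline outcomes. Fully reproducible given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohort`: `genotypes` (patients x SNPs dosage matrix),
#'   `true_labels`, `covariates`, `outcomes`, the planted `grouping`, and the
#'   generating `config`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_patients_ad + config$n_patients_pd
  sim <- simulate_patients(config, n, config$n_patients_ad, "D", 2L)
  study <- ifelse(sim$disease == "AD", "ADNI", "PPMI")
  build_cohort(config, sim, "D", study)
}

#' Generate the paired validation cohort
#'
#' `n_validation` patients drawn from the identical generative law as the
#' discovery cohort (same baseline MAFs, same signature, same effect size) but
#' from an independent random stream. Study labels emulate the validation
#' studies (ROSMAP/IDIBAPS for AD; AETIONOMY PD, DIGPD, ICEBERG for PD).
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohort` with `n_validation` patients.
#' @export
generate_validation_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_validation
  n_ad <- round(n * config$val_ad_fraction)
  if (n == 0) {
    empty <- list(clusters = integer(), dosages = matrix(integer(), 0, sum(config$group_sizes)),
                  disease = character(), age = numeric(), sex = integer(),
                  outcomes = lapply(config$outcome_spec, function(o) numeric()))
    return(build_cohort(config, empty, "V", character()))
  }
  sim <- simulate_patients(config, n, n_ad, "V", 3L)
  study <- with_seed(child_seed(config$seed, 5L), ifelse(
    sim$disease == "AD",
    sample(c("ROSMAP", "IDIBAPS"), n, TRUE, prob = c(237, 21) / 258),
    sample(c("DIGPD", "AETIONOMY_PD", "ICEBERG"), n, TRUE, prob = c(173, 88, 42) / 303)))
  build_cohort(config, sim, "V", study)
}

#' Generate longitudinal outcomes for a cohort
#'
#' For each patient, visits `t = 0, ..., n_visits - 1`. The baseline visit
#' (`t = 0`) anchors the trajectory at the patient's baseline outcome value;
#' follow-up visits add `slope[cluster] * t`, a patient random intercept `b_i`
#' (`ri_sd`) and Gaussian visit noise (`noise_sd`):
#' `outcome(t) = baseline + slope[cluster] * t + b_i + noise` for `t >= 1`.
#' Anchoring the baseline makes the baseline-normalized progression score an
#' exact zero at `t = 0` and keeps the random-intercept variance of the
#' progression scores equal to `ri_sd^2`. The truth slopes are attached as
#' attribute `"true_slopes"`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config the generating [synthetic_config()] (defaults to the one
#'   stored in the cohort).
#' @return data frame with one row per patient-visit: `patient_id`, `cluster`,
#'   `visit`, `value`.
#' @export
generate_longitudinal <- function(cohort, config = cohort$config) {
  if (config$n_visits < 2) stop("configuration error: n_visits must be >= 2")
  ls <- config$longitudinal_spec
  if (length(ls$slopes) != config$k_true)
    stop("configuration error: longitudinal slopes length must equal k_true")
  n <- nrow(cohort$covariates)
  baseline <- cohort$outcomes[[2L]]  # first outcome column (after patient_id)
  with_seed(child_seed(config$seed, 4L), {
    b <- rnorm(n, 0, ls$ri_sd)
    visits <- 0:(config$n_visits - 1L)
    out <- expand.grid(idx = seq_len(n), visit = visits)
    out$patient_id <- cohort$covariates$patient_id[out$idx]
    out$cluster <- cohort$true_labels[out$idx]
    followup <- out$visit > 0
    out$value <- baseline[out$idx]
    out$value[followup] <- out$value[followup] +
      ls$slopes[out$cluster[followup]] * out$visit[followup] +
      b[out$idx[followup]] + rnorm(sum(followup), 0, ls$noise_sd)
    out <- out[order(out$idx, out$visit), c("patient_id", "cluster", "visit", "value")]
    rownames(out) <- NULL
    structure(out, true_slopes = ls$slopes)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$genotypes), "patients x",
      ncol(x$genotypes), "SNPs,", length(x$grouping), "mechanism groups,",
      x$config$k_true, "planted clusters\n")
  invisible(x)
}
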