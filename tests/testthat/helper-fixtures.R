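# Shared fixtures. The default cohort and its burden profile are expensive
# enough (844 patients, 15 autoencoders) to be computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_cohort <- function() memo("default_cohort", generate_cohort(synthetic_config()))

default_burden <- function() memo("default_burden",
  compute_burden_scores(default_cohort(), default_cohort()$grouping,
                        encoder_spec(seed = 11)))

# small, fast two-cluster design for unit tests; 8 mechanisms keep the
# column-permutation null away from the saturation that tiny dimensionalities
# produce (with very few columns even permuted data clusters perfectly)
small_config <- function(effect_delta = 0.3, seed = 77, ...) {
  synthetic_config(n_patients_ad = 70, n_patients_pd = 50, n_validation = 150,
                   k_true = 2,
                   group_sizes = setNames(rep(5L, 8), paste0("G", 1:8)),
                   effect_delta = effect_delta,
                   outcome_spec = list(
                     severity = list(cluster_means = c(0, 1), sd = 1,
                                     beta_age = 0.02, beta_sex = 0.2),
                     null_score = list(cluster_means = c(0, 0), sd = 1,
                                       beta_age = 0, beta_sex = 0)),
                   longitudinal_spec = list(slopes = c(0, 0.5),
                                            ri_sd = 0.3, noise_sd = 0.5),
                   seed = seed, ...)
}
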