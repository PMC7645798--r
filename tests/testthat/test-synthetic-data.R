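test_that("default discovery cohort has the emulated design shape", {
  co <- default_cohort()
  expect_equal(dim(co$genotypes), c(844, 148))
  expect_equal(length(co$grouping), 15)
  expect_equal(sum(lengths(co$grouping)), 148)
  expect_true(all(co$genotypes %in% 0:2))
  expect_equal(nrow(co$covariates), 844)
  expect_equal(nrow(co$outcomes), 844)
  expect_equal(sort(unique(co$true_labels)), 1:4)
  expect_equal(as.vector(table(co$covariates$disease)), c(486, 358))
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$true_labels, b$true_labels)
  expect_identical(a$outcomes, b$outcomes)
  v1 <- generate_validation_cohort(cfg)
  v2 <- generate_validation_cohort(cfg)
  expect_identical(v1$genotypes, v2$genotypes)
  # validation and discovery use disjoint random streams
  expect_false(identical(a$genotypes[1:50, ], v1$genotypes[1:50, ]))
})

test_that("no planted effect means no cluster-wise dosage differences", {
  cfg <- synthetic_config(effect_delta = 0, seed = 5)
  co <- generate_cohort(cfg)
  g1 <- co$true_labels == 1
  z <- vapply(seq_len(ncol(co$genotypes)), function(j) {
    x <- co$genotypes[g1, j]; y <- co$genotypes[!g1, j]
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }, numeric(1))
  expect_true(all(abs(z) < 4))
})

test_that("dosages follow Binomial(2, maf) at large n", {
  cfg <- synthetic_config(n_patients_ad = 5000, n_patients_pd = 5000,
                          n_validation = 0, k_true = 2,
                          group_sizes = c(one = 1), maf_range = c(0.3, 0.3),
                          effect_delta = 0,
                          outcome_spec = list(o = list(cluster_means = c(0, 0),
                                                       sd = 1, beta_age = 0,
                                                       beta_sex = 0)),
                          longitudinal_spec = list(slopes = c(0, 0),
                                                   ri_sd = 0, noise_sd = 1),
                          seed = 8)
  co <- generate_cohort(cfg)
  n <- nrow(co$genotypes)
  f_hat <- mean(co$genotypes) / 2
  expect_lt(abs(f_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * n)))
  # second moment: variance of a Binomial(2, f) draw
  expect_lt(abs(var(as.vector(co$genotypes)) - 2 * 0.3 * 0.7), 0.02)
})

test_that("planted dosage shift equals 2 * effect_delta within 3 SE", {
  cfg <- synthetic_config(n_patients_ad = 3000, n_patients_pd = 3000,
                          n_validation = 0, k_true = 2,
                          group_sizes = c(a = 2, b = 2),
                          maf_range = c(0.2, 0.3), effect_delta = 0.15,
                          outcome_spec = list(o = list(cluster_means = c(0, 0),
                                                       sd = 1, beta_age = 0,
                                                       beta_sex = 0)),
                          longitudinal_spec = list(slopes = c(0, 0),
                                                   ri_sd = 0, noise_sd = 1),
                          seed = 9)
  co <- generate_cohort(cfg)
  # mechanism 1 is burdened in cluster 1 only (cyclic signature)
  j <- 1
  x <- co$genotypes[co$true_labels == 1, j]
  y <- co$genotypes[co$true_labels == 2, j]
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_lt(abs((mean(x) - mean(y)) - 2 * 0.15), 3 * se)
})

test_that("confounders are independent of the planted clusters", {
  ps <- vapply(1:10, function(s) {
    co <- generate_cohort(small_config(seed = 100 + s))
    suppressWarnings(chisq.test(table(co$covariates$sex, co$true_labels))$p.value)
  }, numeric(1))
  # uniform p-values: not systematically small
  expect_gt(mean(ps), 0.2)
  expect_gt(sum(ps > 0.05), 7)
})

test_that("validation cohort matches the paired generative law", {
  co <- generate_validation_cohort(synthetic_config())
  expect_equal(dim(co$genotypes), c(561, 148))
  empty <- generate_validation_cohort(synthetic_config(n_validation = 0))
  expect_s3_class(empty, "synthetic_cohort")
  expect_equal(nrow(empty$genotypes), 0)
  expect_equal(ncol(empty$genotypes), 148)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(cluster_proportions = c(0.5, 0.4)), "simplex|length")
  expect_error(synthetic_config(effect_delta = 0.7), "outside")
  expect_error(synthetic_config(group_sizes = c(3, 0, 4), k_true = 2,
                                cluster_proportions = c(.5, .5)),
               ">= 1")
  expect_error(synthetic_config(snp_ids = c("a", "b")), "snp_ids")
})

test_that("longitudinal outcomes follow the planted slope model", {
  cfg <- small_config()
  cfg$longitudinal_spec <- list(slopes = c(0, 1), ri_sd = 0, noise_sd = 0)
  cfg$n_visits <- 3
  co <- generate_cohort(cfg)
  vt <- generate_longitudinal(co, cfg)
  expect_equal(nrow(vt), nrow(co$genotypes) * 3)
  d <- with(vt, tapply(value, list(patient_id, visit), identity))
  diffs <- d[, 2] - d[, 1]
  cl <- co$true_labels[match(rownames(d), co$covariates$patient_id)]
  expect_equal(unname(diffs[cl == 1]), rep(0, sum(cl == 1)))
  expect_equal(unname(diffs[cl == 2]), rep(1, sum(cl == 2)))

  # identical slopes: per-cluster OLS slopes agree within 3 SE
  cfg2 <- small_config(seed = 31)
  cfg2$longitudinal_spec <- list(slopes = c(0.3, 0.3), ri_sd = 0.2, noise_sd = 0.4)
  co2 <- generate_cohort(cfg2)
  vt2 <- generate_longitudinal(co2, cfg2)
  sl <- lapply(1:2, function(cl) {
    sub <- vt2[vt2$cluster == cl, ]
    fit <- summary(lm(value ~ visit, data = sub))$coefficients
    fit["visit", 1:2]
  })
  se <- sqrt(sl[[1]][2]^2 + sl[[2]][2]^2)
  expect_lt(abs(sl[[1]][1] - sl[[2]][1]), 3 * se)

  cfg$n_visits <- 1
  expect_error(generate_longitudinal(co, cfg), "n_visits")
})

test_that("missingness is generated at the configured MCAR rate", {
  cfg <- small_config(miss_rate = 0.1, seed = 21)
  co <- generate_cohort(cfg)
  expect_gt(mean(is.na(co$genotypes)), 0.07)
  expect_lt(mean(is.na(co$genotypes)), 0.13)
})
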