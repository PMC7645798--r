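sim_assoc <- function(n = 300, k = 4, shift = 0, seed = 1) {
  set.seed(seed)
  cl <- sample(1:k, n, TRUE)
  age <- rnorm(n, 70, 8)
  sex <- factor(sample(c("F", "M"), n, TRUE))
  y <- rnorm(n) + shift * (cl == 2)
  list(cl = factor(cl), age = age, sex = sex, y = y)
}

test_that("stepwise confounder selection matches exhaustive best-AIC subsets", {
  set.seed(2)
  n <- 400
  cl <- factor(sample(1:3, n, TRUE))
  conf1 <- rnorm(n, as.integer(cl))          # real confounder, strong
  conf2 <- rnorm(n)                          # noise
  conf3 <- rnorm(n)                          # noise
  cand <- data.frame(conf1 = conf1, conf2 = conf2, conf3 = conf3)
  sel <- select_confounders(cl, cand)
  # exhaustive oracle over all 8 subsets
  subsets <- unlist(lapply(0:3, function(m) combn(names(cand), m, simplify = FALSE)),
                    recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    f <- if (length(s)) reformulate(s, ".cluster") else .cluster ~ 1
    AIC(nnet::multinom(f, data = data.frame(.cluster = cl, cand), trace = FALSE))
  }, numeric(1))
  best <- subsets[[which.min(aics)]]
  expect_setequal(sel$selected, best)
  expect_lte(sel$aic_final, sel$aic_null)
})

test_that("pure-noise candidates are mostly rejected by the AIC", {
  empty <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    cl <- factor(sample(1:4, 500, TRUE))
    cand <- data.frame(n1 = rnorm(500), n2 = rnorm(500))
    length(select_confounders(cl, cand)$selected) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.7)
})

test_that("separating candidates are excluded with a warning", {
  cl <- factor(rep(1:2, each = 30))
  cand <- data.frame(copy = factor(cl), ok = rnorm(60))
  expect_warning(sel <- select_confounders(cl, cand), "separat")
  expect_false("copy" %in% sel$selected)
})

test_that("a planted 1-SD shift in one cluster is detected by the LRT", {
  d <- sim_assoc(n = 400, shift = 1, seed = 3)
  res <- outcome_association(d$y, d$cl, outcome_name = "score")
  expect_lt(res$p, 0.01)
  expect_s3_class(res$pairwise, "data.frame")
  expect_equal(nrow(res$pairwise), choose(4, 2))
  # pairwise Wald flags pairs involving the shifted cluster most strongly
  pw <- res$pairwise
  with2 <- pw$cluster_a == "2" | pw$cluster_b == "2"
  expect_lt(min(pw$p[with2]), min(pw$p[!with2]))
})

test_that("the two-cluster multinomial LRT equals the binomial logistic LRT", {
  d <- sim_assoc(n = 200, k = 2, shift = 0.8, seed = 4)
  res <- outcome_association(d$y, d$cl, outcome_name = "score")
  g0 <- glm(d$cl ~ 1, family = binomial)
  g1 <- glm(d$cl ~ d$y, family = binomial)
  lrt_glm <- g0$deviance - g1$deviance
  expect_equal(res$lrt_stat, lrt_glm, tolerance = 1e-8)
})

test_that("confounder adjustment removes confounder-driven false positives", {
  hits_raw <- 0; hits_adj <- 0
  for (s in 1:30) {
    set.seed(200 + s)
    n <- 300
    conf <- rnorm(n)
    # clusters depend on the confounder; outcome depends ONLY on the confounder
    cl <- factor(1 + (plogis(1.5 * conf) > runif(n)))
    y <- conf + rnorm(n, 0, 0.5)
    raw <- outcome_association(y, cl, outcome_name = "y")
    adj <- outcome_association(y, cl, confounders = data.frame(conf = conf),
                               outcome_name = "y")
    hits_raw <- hits_raw + (raw$p < 0.05)
    hits_adj <- hits_adj + (adj$p < 0.05)
  }
  expect_gt(hits_raw / 30, 0.5)   # confounding induces false positives
  expect_lte(hits_adj / 30, 0.15) # adjustment restores near-nominal behavior
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, NA)), "NA")
  expect_error(adjust_bh(c(0.1, 1.2)), "0,1")
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), bf_bh(p))
  }
  # monotone and never below raw
  p <- runif(50)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("BH adjustment is invariant to input order", {
  set.seed(6)
  p <- runif(30)
  o <- sample(30)
  expect_equal(adjust_bh(p)[o], adjust_bh(p[o]))
})

test_that("progression scores are zero at baseline by construction", {
  cfg <- small_config()
  co <- generate_cohort(cfg)
  vt <- generate_longitudinal(co, cfg)
  res <- longitudinal_association(vt)
  expect_equal(res$ri_variance >= 0, TRUE)
  base <- vt[vt$visit == 0, ]
  prog0 <- (base$value - base$value) / sd(base$value)
  expect_equal(prog0, rep(0, nrow(base)))
})

test_that("zero random-intercept truth reduces to the OLS fit", {
  cfg <- small_config(seed = 41)
  cfg$longitudinal_spec <- list(slopes = c(0, 0.4), ri_sd = 0, noise_sd = 0.6)
  co <- generate_cohort(cfg)
  vt <- generate_longitudinal(co, cfg)
  res <- suppressWarnings(longitudinal_association(vt))
  expect_lte(res$ri_variance, 0.05)
  b0 <- vt[vt$visit == 0, ]
  vt$prog <- (vt$value - b0$value[match(vt$patient_id, b0$patient_id)]) /
    sd(b0$value)
  vt <- vt[vt$visit > 0, ]  # the model is fit on follow-up visits
  vt$.cluster <- factor(vt$cluster)
  vt$.time <- if (res$time_coding == "categorical") factor(vt$visit) else vt$visit
  ols <- coef(lm(prog ~ .cluster * .time, data = vt))
  expect_equal(unname(res$fixed_effects), unname(ols[names(res$fixed_effects)]),
               tolerance = 1e-3)
})

test_that("a planted slope difference is detected by the mixed model", {
  cfg <- small_config(seed = 55)
  cfg$longitudinal_spec <- list(slopes = c(0, 0.5), ri_sd = 0.3, noise_sd = 0.5)
  cfg$n_visits <- 3
  co <- generate_cohort(cfg)
  vt <- generate_longitudinal(co, cfg)
  res <- longitudinal_association(vt)
  expect_lt(min(res$p_cluster, res$p_interaction), 0.05)
})

test_that("association battery pools p-values and adjusts jointly", {
  co <- generate_cohort(small_config(seed = 60))
  bat <- association_battery(co$outcomes[, -1], co$true_labels,
                             candidates = co$covariates[, c("age", "sex")])
  expect_true(all(c("severity", "null_score") %in% bat$table$outcome))
  expect_true(all(bat$table$p_adjusted >= bat$table$p))
  expect_equal(bat$table$p_adjusted, adjust_bh(bat$table$p))
  # planted severity shift found, null outcome not
  lrt <- bat$table[bat$table$test == "LRT", ]
  expect_lt(lrt$p[lrt$outcome == "severity"], 0.01)
})

test_that("imaging-style batteries can fix the confounder set to age and sex", {
  co <- generate_cohort(small_config(seed = 61))
  bat <- association_battery(co$outcomes[, "severity", drop = FALSE],
                             co$true_labels,
                             candidates = co$covariates[, c("age", "sex")],
                             fixed_confounders = c("age", "sex"))
  expect_null(bat$selection)
  expect_true(nrow(bat$table) >= 1)
})

test_that("undersized clusters are rejected", {
  expect_error(outcome_association(rnorm(10), factor(c(rep(1, 8), 2, 2))),
               ">= 5")
})
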