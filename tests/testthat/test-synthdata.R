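test_that("generator is a pure function of its configuration", {
  cf <- sim_config(n_probes = 40, n_marker_probes = 12, seed = 7)
  a <- simulate_cohort(cf)
  b <- simulate_cohort(cf)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$methylation$detection_p, b$methylation$detection_p)
  expect_identical(a$cohort$Y, b$cohort$Y)
  expect_identical(a$cohort$C, b$cohort$C)
  expect_identical(a$truth, b$truth)
  # a different seed actually changes the data
  c2 <- simulate_cohort(sim_config(n_probes = 40, n_marker_probes = 12, seed = 8))
  expect_false(identical(a$cohort$Y, c2$cohort$Y))
})

test_that("generated cohorts satisfy their structural invariants", {
  sc <- simulate_cohort(sim_config(n_probes = 60, n_marker_probes = 18, seed = 3))
  props <- sc$cohort$C[, c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")]
  expect_true(all(props >= 0))
  expect_equal(unname(rowSums(props)), rep(1, sc$cohort$n))
  expect_true(all(sc$methylation$values > 0 & sc$methylation$values < 1))
  expect_true(all(sc$truth$indices %in% seq_len(60)))
  expect_equal(sc$truth$log_or_acme, sc$config$alpha_xm * sc$config$beta_my)
  # exposure prevalence near the configured marginal
  p_marg <- (103 * 0.466 + 174 * 0.218) / 277
  expect_lt(abs(mean(sc$cohort$X) - p_marg), 0.1)
})

test_that("all-null configuration gives a null exposure-outcome association", {
  cf <- sim_config(n_cases = 1000, n_controls = 1000, n_probes = 5,
                   n_true_mediators = 0, alpha_xm = numeric(0),
                   beta_my = numeric(0), theta_direct = 0,
                   confounder_strength = 0, n_marker_probes = 12, seed = 21)
  sc <- simulate_cohort(cf)
  fit <- glm(sc$cohort$Y ~ sc$cohort$X, family = binomial)
  z <- coef(summary(fit))["sc$cohort$X", ]
  expect_lt(abs(z["Estimate"]), 3 * z["Std. Error"])
})

test_that("truth record carries the closed-form odds-ratio products", {
  cf <- sim_config(n_cases = 103, n_controls = 174, n_probes = 10,
                   n_true_mediators = 1, alpha_xm = 0.5, beta_my = 0.4,
                   theta_direct = 0.19, n_marker_probes = 12, seed = 5)
  sc <- simulate_cohort(cf)
  expect_equal(sc$truth$log_or_acme, 0.2)
  expect_equal(sc$truth$log_or_ade, 0.19)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(n_probes = 2, n_true_mediators = 3,
                          alpha_xm = 1:3, beta_my = 1:3, seed = 1),
               "n_true_mediators")
  expect_error(sim_config(alpha_xm = c(Inf, 1, 1, 1), seed = 1), "alpha_xm")
  expect_error(sim_config(noise_sd = 0, seed = 1), "noise_sd")
  expect_error(sim_config(smoking_prevalence_case = 1.2, seed = 1), "prevalence")
  expect_error(sim_config(n_probes = 10), "seed")
})

test_that("exposure-mediator effect is calibrated over replicates", {
  # empirical X -> M regression slope matches the configured effect
  slopes <- vapply(1:300, function(s) {
    sc <- simulate_cohort(sim_config(n_probes = 1, n_true_mediators = 1,
                                     alpha_xm = 0.5, beta_my = 0,
                                     theta_direct = 0, n_marker_probes = 12,
                                     seed = s))
    m <- log2(sc$methylation$values[1, ] / (1 - sc$methylation$values[1, ]))
    unname(coef(lm(m ~ sc$cohort$X))[2])
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.5), 3 * mc_se)
})

test_that("planted detection artifacts are exactly what the filters find", {
  m <- make_test_meth(n_probes = 100, n_samples = 50, seed = 2)

  clean <- plant_detection_artifacts(m, 0, 0, seed = 4)
  expect_length(attr(clean, "planted")$bad_probes, 0)
  expect_no_error(suppressMessages(filter_probes(clean)))
  expect_equal(nrow(suppressMessages(filter_probes(clean))$values), 100)
  expect_equal(ncol(suppressMessages(filter_samples(clean))$values), 50)

  bad <- plant_detection_artifacts(m, frac_bad_probes = 0.05,
                                   frac_bad_samples = 0.04, seed = 4)
  planted <- attr(bad, "planted")
  expect_length(planted$bad_probes, 5)
  expect_length(planted$bad_samples, 2)
  fs <- suppressMessages(filter_samples(bad))
  expect_setequal(attr(fs, "removed"), planted$bad_samples)
  fp <- suppressMessages(filter_probes(fs))
  expect_setequal(attr(fp, "removed"), planted$bad_probes)
})

test_that("simulated reference panels have the standard leukocyte structure", {
  ref <- simulate_reference(n_celltypes = 6, n_marker_probes = 30, seed = 9)
  expect_equal(ref$cell_type_names, c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran"))
  expect_true(all(ref$profiles > 0 & ref$profiles < 1))
  # each marker is hyper-methylated in exactly one cell type
  owners <- apply(ref$profiles, 1, function(r) sum(r > 0.5))
  expect_true(all(owners == 1))
})

test_that("a 50/50 mixture of two reference profiles deconvolves to (0.5, 0.5)", {
  ref <- simulate_reference(n_celltypes = 6, n_marker_probes = 36, seed = 9)
  mix <- 0.5 * ref$profiles[, "CD8T"] + 0.5 * ref$profiles[, "Gran"]
  v <- cbind(S1 = mix)
  m <- meth_matrix(pmin(pmax(v, 1e-4), 1 - 1e-4), scale = "beta")
  est <- estimate_cell_proportions(m, ref)$proportions
  expect_lt(abs(est[1, "CD8T"] - 0.5), 0.05)
  expect_lt(abs(est[1, "Gran"] - 0.5), 0.05)
  expect_lt(max(est[1, c("CD4T", "NK", "Bcell", "Mono")]), 0.05)
})
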