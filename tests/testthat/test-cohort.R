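test_that("configuration validation rejects bad inputs", {
  expect_error(cohort_config(n_encounters = 0), "positive count")
  expect_error(cohort_config(missingness_rate = 1), "\\[0, 1\\)")
  expect_error(cohort_config(guideline_scenario_mix = c(copd_exacerbation = 0.5,
                                                        none = 0.6)),
               "sum to 1")
  expect_error(cohort_config(effect_coefficients = c(not_a_covariate = 1)),
               "unknown covariates")
  expect_error(cohort_config(effect_coefficients = c(1, 2)), "named")
})

test_that("same config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_encounters = 150, seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$encounters, c2$encounters)
  expect_identical(c1$observations, c2$observations)
  c3 <- generate_cohort(cohort_config(n_encounters = 150, seed = 10))
  expect_false(identical(c1$encounters$imv, c3$encounters$imv))
})

test_that("zero treatment effect gives exactly zero individual effects", {
  cfg <- cohort_config(n_encounters = 400, seed = 3,
                       effect_coefficients = c("(Intercept)" = 0),
                       unmeasured_confounding_strength = 0)
  coh <- generate_cohort(cfg, timeseries = FALSE)
  expect_identical(mean(coh$encounters$oracle_true_ite), 0)
  expect_identical(oracle_ate(cfg, 1e4), 0)
})

test_that("homogeneous probability-scale shift yields that shift as the ATE", {
  cfg <- cohort_config(n_encounters = 10, seed = 3, baseline_risk = 0.3,
                       effect_coefficients = c("(Intercept)" = 0.05),
                       outcome_coefficients = c(sofa_z = 0),
                       measured_confounding_strength = 0,
                       unmeasured_confounding_strength = 0,
                       effect_type = "prob_shift")
  expect_equal(oracle_ate(cfg, 1e4), 0.05, tolerance = 1e-12)
})

test_that("oracle ATE matches the mean per-record true effect at large n", {
  cfg <- cohort_config(n_encounters = 200000, seed = 5)
  coh <- generate_cohort(cfg, timeseries = FALSE)
  expect_lt(abs(oracle_ate(cfg, 1e6) - mean(coh$encounters$oracle_true_ite)),
            1e-3)
})

test_that("empirical ATE is within 3 Monte-Carlo SEs of the oracle ATE", {
  cfg <- cohort_config(n_encounters = 20000, seed = 17)
  coh <- generate_cohort(cfg, timeseries = FALSE)
  ite <- coh$encounters$oracle_true_ite
  se <- sd(ite) / sqrt(length(ite))
  expect_lt(abs(mean(ite) - oracle_ate(cfg)), 3 * se)
})

test_that("confounding is real: naive arm contrast is biased at n = 20000", {
  cfg <- cohort_config(n_encounters = 20000, seed = 17)
  coh <- generate_cohort(cfg, timeseries = FALSE)
  enc <- coh$encounters
  t1 <- enc$treatment_received == "NIV"
  diff_means <- mean(enc$imv[t1]) - mean(enc$imv[!t1])
  se <- sqrt(var(enc$imv[t1]) / sum(t1) + var(enc$imv[!t1]) / sum(!t1))
  expect_gt(abs(diff_means - oracle_ate(cfg)), 2 * se)
})

test_that("observed IMV prevalence sits in the configured band", {
  coh <- generate_cohort(cohort_config(n_encounters = 5000, seed = 23),
                         timeseries = FALSE)
  expect_lt(abs(mean(coh$encounters$imv) - 0.27), 0.05)
})

test_that("scenario flags drive guideline-triggering snapshot fields", {
  coh <- generate_cohort(cohort_config(n_encounters = 4000, seed = 8),
                         timeseries = FALSE)
  enc <- coh$encounters
  copd <- enc[enc$copd_exacerbation, ]
  acid <- copd$ph <= 7.35 & copd$paco2 > 45
  expect_gt(mean(acid), 0.6)
  other <- enc[enc$scenario == "none", ]
  expect_lt(mean(other$ph <= 7.35 & other$paco2 > 45), 0.2)
})

test_that("missingness injection drops the configured fraction, reproducibly", {
  obs <- data.frame(encounter_id = "E1", variable = "hr",
                    hours_before_t0 = seq_len(10000) / 300,
                    value = rnorm(10000))
  expect_identical(inject_missingness(obs, 0, seed = 1), obs)
  d1 <- inject_missingness(obs, 0.5, seed = 2)
  expect_lt(abs(1 - nrow(d1) / nrow(obs) - 0.5), 0.02)
  expect_identical(d1, inject_missingness(obs, 0.5, seed = 2))
  expect_error(inject_missingness(obs, 1), "\\[0, 1\\)")
})

test_that("cohorts round-trip through CSV including oracle columns", {
  coh <- small_cohort(n = 40, seed = 12)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$encounters$oracle_true_ite,
               coh$encounters$oracle_true_ite, tolerance = 1e-12)
  expect_equal(back$encounters$treatment_received,
               coh$encounters$treatment_received)
  expect_equal(nrow(back$observations), nrow(coh$observations))
  expect_equal(back$observations$value, coh$observations$value,
               tolerance = 1e-12)
})

test_that("malformed cohort files fail with a column-naming parse error", {
  coh <- small_cohort(n = 10, seed = 12)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  enc <- read.csv(file.path(dir, "encounters.csv"))
  enc$imv <- NULL
  write.csv(enc, file.path(dir, "encounters.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "imv")
})

test_that("estimator-facing feature assembly never consumes oracle columns", {
  coh <- small_cohort(n = 30, seed = 5)
  fs <- assemble_features(coh)
  expect_false(any(startsWith(colnames(fs$features), "oracle_")))
  expect_false(any(grepl("oracle", fs$feature_names)))
  stripped <- strip_oracle(coh$encounters)
  expect_false(any(startsWith(names(stripped), "oracle_")))
  expect_true(any(startsWith(names(coh$encounters), "oracle_")))
})
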