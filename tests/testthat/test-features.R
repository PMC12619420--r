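mk_obs <- function(var, hb, val) {
  data.frame(variable = var, hours_before_t0 = hb, value = val,
             stringsAsFactors = FALSE)
}

test_that("hourly resampling places and averages observations correctly", {
  g <- resample_hourly(mk_obs("ph", 2.5, 7.3), horizon_hours = 48)
  expect_equal(unname(g$grid["ph", "-2"]), 7.3)
  expect_equal(sum(!is.na(g$grid)), 1L)

  g <- resample_hourly(mk_obs(c("hr", "hr"), c(3.2, 3.9), c(4, 6)), 48)
  expect_equal(unname(g$grid["hr", "-3"]), 5)

  expect_warning(resample_hourly(mk_obs("hr", -1, 80), 48), "after T0")
})

test_that("per-bin means equal a brute-force group-by recomputation", {
  set.seed(7)
  obs <- mk_obs(sample(c("a", "b", "c"), 1000, TRUE),
                runif(1000, 0, 48), rnorm(1000))
  g <- resample_hourly(obs, 48)
  oracle <- aggregate(value ~ variable + bin,
                      transform(obs, bin = -floor(hours_before_t0)), mean)
  for (i in seq_len(nrow(oracle)))
    expect_equal(unname(g$grid[oracle$variable[i],
                               as.character(oracle$bin[i])]),
                 oracle$value[i])
  expect_equal(sum(!is.na(g$grid)), nrow(oracle))
})

test_that("imputation carries forward up to 24 h then falls back to the mean", {
  pm <- c(ph = 7.40)
  g <- resample_hourly(mk_obs("ph", 3.5, 7.2), 48)
  gi <- impute_grid(g, pm)
  expect_equal(unname(gi$grid["ph", c("-2", "-1", "0")]), rep(7.2, 3))

  ## last observation 25 h before the last bin: population mean there
  g <- resample_hourly(mk_obs("ph", 25.5, 7.2), 48)
  gi <- impute_grid(g, pm)
  expect_equal(unname(gi$grid["ph", "0"]), 7.40)   # gap 25 > 24
  expect_equal(unname(gi$grid["ph", "-1"]), 7.2)   # gap 24 <= 24 (inclusive)
  expect_equal(unname(gi$grid["ph", "-30"]), 7.40) # before first observation

  expect_error(impute_grid(g, c(other = 1)), "ph")
})

test_that("imputation matches an independent per-cell re-implementation", {
  set.seed(21)
  for (rep in 1:5) {
    obs <- mk_obs("x", sort(runif(8, 0, 48)), rnorm(8))
    pm <- c(x = 99)
    g <- resample_hourly(obs, 48)
    gi <- impute_grid(g, pm)
    row <- g$grid["x", ]
    oracle <- vapply(seq_along(row), function(j) {
      if (!is.na(row[j])) return(row[j])
      prev <- which(!is.na(row[seq_len(j)]))
      if (length(prev) == 0) return(99)
      k <- max(prev)
      if (j - k <= 24) row[k] else 99
    }, numeric(1))
    expect_equal(unname(gi$grid["x", ]), unname(oracle))
  }
})

test_that("imputation is idempotent and preserves observed cells", {
  set.seed(4)
  obs <- mk_obs(rep(c("a", "b"), 20), runif(40, 0, 48), rnorm(40))
  pm <- c(a = 0.5, b = -0.5)
  g <- resample_hourly(obs, 48)
  g1 <- impute_grid(g, pm)
  g2 <- impute_grid(g1, pm)
  expect_identical(g1$grid, g2$grid)
  expect_identical(g1$measured_mask, g$measured_mask)
  expect_equal(g1$grid[g$measured_mask], g$grid[g$measured_mask])
  expect_false(anyNA(g1$grid))
})

test_that("time since last measurement uses the most recent bin, with sentinel", {
  g <- resample_hourly(mk_obs("a", 3.5, 1), 48, variables = c("a", "b"))
  tl <- tslm(g)
  expect_equal(unname(tl["a"]), 3)
  expect_equal(unname(tl["b"]), 49)   # never measured, horizon 48
  g <- resample_hourly(mk_obs("a", 0.5, 1), 48)
  expect_equal(unname(tslm(g)["a"]), 0)
})

test_that("local trend is the OLS slope over the trailing window", {
  obs <- mk_obs(rep("a", 6), 5.5:0.5, 1:6)
  g <- impute_grid(resample_hourly(obs, 48), c(a = 0))
  expect_equal(unname(local_trend(g, 6)["a"]), 1)

  g2 <- impute_grid(resample_hourly(mk_obs("a", 3.5, 2), 48), c(a = 2))
  expect_equal(unname(local_trend(g2, 6)["a"]), 0)

  set.seed(9)
  vals <- rnorm(6)
  g3 <- impute_grid(resample_hourly(mk_obs(rep("a", 6), 5.5:0.5, vals), 48),
                    c(a = 0))
  x <- -5:0
  slope_oracle <- sum((x - mean(x)) * (vals - mean(vals))) / sum((x - mean(x))^2)
  expect_equal(unname(local_trend(g3, 6)["a"]), slope_oracle)
  expect_error(local_trend(g3, 1), "at least 2")
})

test_that("baseline is the earliest observed value, population mean if none", {
  g <- resample_hourly(mk_obs(c("a", "a"), c(40.5, 2.5), c(10, 20)), 48,
                       variables = c("a", "b"))
  b <- baseline_values(g, c(a = 0, b = 77))
  expect_equal(unname(b["a"]), 10)
  expect_equal(unname(b["b"]), 77)
})

test_that("assembled features have fixed dimension, order invariance, no gaps", {
  coh <- small_cohort(n = 60, seed = 14)
  fs <- assemble_features(coh)
  n_vars <- length(unique(coh$observations$variable))
  expect_equal(ncol(fs$features), 4 * n_vars + 12)
  expect_false(anyNA(fs$features))
  expect_equal(rownames(fs$features), coh$encounters$encounter_id)

  ## permuting observation order changes nothing
  coh2 <- coh
  set.seed(1)
  coh2$observations <- coh$observations[sample(nrow(coh$observations)), ]
  fs2 <- assemble_features(coh2)
  expect_equal(fs2$features, fs$features)
})

test_that("population means come from the training split only", {
  coh <- small_cohort(n = 50, seed = 15)
  sp <- split_cohort(coh, 0.8, seed = 2)
  m_train <- population_means(coh$observations, sp$train_ids)
  fs <- assemble_features(coh, train_ids = sp$train_ids)
  expect_equal(fs$means, m_train)
  m_all <- population_means(coh$observations)
  expect_false(isTRUE(all.equal(m_train, m_all)))
})
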