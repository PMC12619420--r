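test_that("concordance labels follow the recommendation/received pair", {
  expect_equal(label_concordance("NIV", "NIV"), "concordant")
  expect_equal(label_concordance("HFNC", "NIV"), "discordant")
  expect_equal(label_concordance("Indifferent", "HFNC"), "excluded")
  fin <- structure(list(modality = "Indifferent", status = "deferred"),
                   class = "final_recommendation")
  expect_equal(label_concordance(fin, "HFNC"), "excluded")
  expect_error(label_concordance("NIV", "oxygen"), "NIV or HFNC")
})

test_that("printed rates reproduce from counts with half-up rounding", {
  expect_equal(rate_pct(46, 188), 24.47)
  expect_equal(rate_pct(9, 17), 52.94)
  expect_equal(rate_pct(0, 50), 0)
  expect_true(is.na(rate_pct(0, 0)))
  ## half-up, not half-even
  expect_equal(rate_pct(1, 8), 12.50)
  expect_equal(round_half_up(0.125 * 100, 2), 12.5)
  expect_equal(round_half_up(-3.405, 2), -3.41)
})

test_that("relative change metrics reproduce the published stratified table", {
  ## IMV outcome strata (total; concordant; discordant counts)
  expect_equal(relative_reduction(252, 891, 50, 220), 19.64)
  expect_equal(relative_increase(252, 891, 202, 671), 6.44)
  expect_equal(relative_reduction(70, 252, 43, 172), 10.00)
  expect_equal(relative_increase(70, 252, 27, 80), 21.50)
  expect_equal(relative_reduction(197, 759, 58, 274), 18.44)
  expect_equal(relative_increase(197, 759, 139, 485), 10.42)
  expect_equal(relative_reduction(55, 205, 46, 188), 8.80)
  expect_equal(relative_increase(55, 205, 9, 17), 97.33)
  ## mortality/hospice strata
  expect_equal(relative_reduction(326, 891, 75, 220), 6.83)
  expect_equal(relative_increase(326, 891, 251, 671), 2.24)
  expect_equal(relative_reduction(75, 252, 52, 172), -1.58)
  expect_equal(relative_increase(75, 252, 23, 80), -3.40)
  expect_equal(relative_reduction(261, 759, 81, 274), 14.03)
  expect_equal(relative_increase(261, 759, 180, 485), 7.93)
  expect_equal(relative_reduction(52, 205, 47, 188), 1.44)
  expect_equal(relative_increase(52, 205, 5, 17), 15.95)
})

test_that("relative metrics are zero iff the group rates coincide", {
  expect_equal(relative_reduction(20, 100, 10, 50), 0)
  expect_equal(relative_increase(20, 100, 10, 50), 0)
  expect_true(is.na(relative_reduction(0, 100, 0, 50)))
})

test_that("tabulation matches a brute-force recount and keeps invariants", {
  set.seed(26)
  coh <- small_cohort(n = 400, seed = 26, timeseries = FALSE)
  enc <- coh$encounters
  rec <- data.frame(encounter_id = enc$encounter_id,
                    modality = sample(c("NIV", "HFNC", "Indifferent"),
                                      400, TRUE, prob = c(.45, .35, .2)))
  strata <- tabulate_concordance(enc, rec[rec$modality != "Indifferent", ],
                                 "model")
  expect_equal(nrow(strata), 4)
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    y <- if (st$outcome_name == "IMV") enc$imv else enc$mortality_or_hospice
    sel <- rec$modality == st$recommendation
    conc <- sel & enc$treatment_received == st$recommendation
    expect_equal(st$n_total, sum(sel))
    expect_equal(st$e_total, sum(y[sel]))
    expect_equal(st$n_concordant, sum(conc))
    expect_equal(st$e_concordant, sum(y[conc]))
    expect_equal(st$n_concordant + st$n_discordant, st$n_total)
    expect_equal(st$e_concordant + st$e_discordant, st$e_total)
  }
  expect_error(tabulate_concordance(enc,
                                    data.frame(encounter_id = "nope",
                                               modality = "NIV")),
               "unmatched")
})

test_that("logistic coefficients match an independent IRLS solve", {
  set.seed(27)
  n <- 200
  rows <- data.frame(
    concordant = rbinom(n, 1, 0.5), age = rnorm(n, 60, 15),
    gender = rbinom(n, 1, 0.55), cci = rpois(n, 2), sofa = rpois(n, 2),
    ventio_score = runif(n))
  lp <- -1 + log(0.65) * rows$concordant - 0.01 * rows$age + 0.2 * rows$sofa
  rows$outcome <- rbinom(n, 1, plogis(lp))
  eff <- adjusted_association(rows)

  ## hand-rolled iteratively-reweighted least squares
  X <- cbind(1, rows$concordant, rows$age, rows$gender, rows$cci,
             rows$sofa, rows$ventio_score)
  y <- rows$outcome
  beta <- rep(0, ncol(X))
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  expect_equal(unname(log(eff$odds_ratio)), drop(beta), tolerance = 1e-6)
  ## Wald interval construction
  se <- sqrt(diag(solve(crossprod(X, drop(plogis(X %*% beta) *
                                            (1 - plogis(X %*% beta))) * X))))
  expect_equal(unname(log(eff$ci_high) - log(eff$odds_ratio)),
               1.96 * se, tolerance = 1e-5)
})

test_that("a null association gives an odds ratio near one", {
  set.seed(28)
  n <- 5000
  rows <- data.frame(
    outcome = rbinom(n, 1, 0.3), concordant = rbinom(n, 1, 0.5),
    age = rnorm(n, 60, 15), gender = rbinom(n, 1, 0.5),
    cci = rpois(n, 2), sofa = rpois(n, 2), ventio_score = runif(n))
  eff <- adjusted_association(rows)
  or <- eff$odds_ratio[eff$term == "concordant"]
  expect_gt(or, 0.85)
  expect_lt(or, 1.18)
})

test_that("the 95% CI covers a known concordance effect in >= 90% of fits", {
  set.seed(29)
  true_or <- 0.65
  hits <- 0
  for (r in 1:100) {
    n <- 5000
    rows <- data.frame(
      concordant = rbinom(n, 1, 0.5), age = rnorm(n, 60, 15),
      gender = rbinom(n, 1, 0.5), cci = rpois(n, 2), sofa = rpois(n, 2),
      ventio_score = runif(n))
    lp <- -0.8 + log(true_or) * rows$concordant - 0.01 * rows$age +
      0.15 * rows$sofa + 0.5 * rows$ventio_score
    rows$outcome <- rbinom(n, 1, plogis(lp))
    eff <- adjusted_association(rows)
    ci <- eff[eff$term == "concordant", ]
    if (ci$ci_low <= true_or && true_or <= ci$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("constructed protective concordance is detected reliably", {
  set.seed(30)
  detected <- 0
  for (r in 1:100) {
    n <- 2000
    conc <- rbinom(n, 1, 0.5)
    base <- plogis(-0.9)
    p <- ifelse(conc == 1, base / 2, base)   # concordant care halves risk
    rows <- data.frame(
      outcome = rbinom(n, 1, p), concordant = conc,
      age = rnorm(n, 60, 15), gender = rbinom(n, 1, 0.5),
      cci = rpois(n, 2), sofa = rpois(n, 2), ventio_score = runif(n))
    eff <- adjusted_association(rows)
    if (eff$odds_ratio[eff$term == "concordant"] < 1) detected <- detected + 1
  }
  expect_gt(detected / 100, 0.95)
})

test_that("validation of the regression inputs", {
  rows <- data.frame(outcome = rbinom(30, 1, .5), concordant = rbinom(30, 1, .5),
                     age = rnorm(30), gender = rbinom(30, 1, .5),
                     cci = rpois(30, 2), sofa = rpois(30, 2),
                     ventio_score = runif(30))
  expect_error(adjusted_association(rows[1:10, ]), "at least 25")
  rows$age[3] <- NA
  expect_error(adjusted_association(rows), "missing covariate")
  rows$age <- NULL
  expect_error(adjusted_association(rows), "age")
})

test_that("report files round-trip", {
  coh <- small_cohort(n = 120, seed = 33, timeseries = FALSE)
  enc <- coh$encounters
  set.seed(33)
  rec <- data.frame(encounter_id = enc$encounter_id,
                    modality = sample(c("NIV", "HFNC"), 120, TRUE))
  strata <- tabulate_concordance(enc, rec, "model")
  rows <- data.frame(outcome = as.numeric(enc$imv),
                     concordant = as.numeric(rec$modality ==
                                               enc$treatment_received),
                     age = enc$age, gender = enc$gender, cci = enc$cci,
                     sofa = enc$sofa, ventio_score = enc$ventio_score)
  eff <- adjusted_association(rows)
  dir <- withr::local_tempdir()
  build_report(strata, eff, dir)
  back <- read_report(dir)
  expect_equal(as.data.frame(back$strata), as.data.frame(strata),
               tolerance = 1e-9)
  expect_equal(back$effects$odds_ratio, eff$odds_ratio, tolerance = 1e-9)

  ## empty strata: headers-only files still read back
  empty <- strata[0, ]
  dir2 <- withr::local_tempdir()
  build_report(empty, NULL, dir2)
  back2 <- read_report(dir2)
  expect_equal(nrow(back2$strata), 0)
})
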