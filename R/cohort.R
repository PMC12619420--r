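## ---- internal population simulator ----------------------------------------
## Draws statics, scenario flags, guideline snapshot fields, the latent
## confounder U and the potential-outcome probabilities for n encounters.
## Consumes the current RNG stream; callers are responsible for seeding.
.simulate_population <- function(config, n) {
  sev <- rnorm(n)                       # latent illness severity
  u <- rnorm(n)                         # unmeasured confounder

  age <- pmin(pmax(round(rnorm(n, 62, 16)), 18), 100)
  gender <- ifelse(runif(n) < 0.58, "M", "F")
  cci <- stats::rpois(n, 2.4)
  sofa <- stats::rpois(n, exp(0.55 + 0.5 * sev))
  ventio_score <- sigmoid(-1.2 + 0.9 * sev + 0.4 * rnorm(n))

  mix <- config$guideline_scenario_mix
  scenario <- sample(names(mix), n, replace = TRUE, prob = mix)

  flag <- function(s) scenario == s
  copd_ex <- flag("copd_exacerbation")
  edema <- flag("cardiogenic_edema")
  denovo <- flag("de_novo_hypoxemic")
  postex <- flag("post_extubation")
  immuno <- flag("immunocompromised")

  ## comorbidity flags correlated with scenarios
  chf <- runif(n) < ifelse(edema, 0.80, 0.22)
  copd <- runif(n) < ifelse(copd_ex, 0.90, 0.12)

  ## snapshot numerics: scenario-conditional truncated normals so the rule
  ## engine sees guideline-triggering combinations at known frequencies
  pick <- function(means, sds) {
    m <- means[scenario]; s <- sds[scenario]
    list(m = m, s = s)
  }
  sc <- .scenario_names
  ph_m <- setNames(c(7.28, 7.37, 7.43, 7.40, 7.42, 7.40), sc)
  ph_s <- setNames(c(0.06, 0.06, 0.05, 0.04, 0.04, 0.05), sc)
  pc_m <- setNames(c(60, 42, 36, 40, 38, 41), sc)
  pc_s <- setNames(c(10, 8, 6, 5, 5, 6), sc)
  rr_m <- setNames(c(28, 30, 32, 24, 26, 22), sc)
  rr_s <- setNames(c(5, 5, 6, 5, 5, 4), sc)
  sp_m <- setNames(c(90, 88, 86, 93, 91, 94), sc)
  sp_s <- setNames(c(4, 5, 5, 3, 4, 3), sc)
  fi_m <- setNames(c(0.45, 0.60, 0.70, 0.40, 0.45, 0.35), sc)
  fi_s <- setNames(c(0.15, 0.20, 0.20, 0.10, 0.15, 0.10), sc)

  p <- pick(ph_m, ph_s)
  ph <- rtruncnorm(n, p$m, p$s, 6.8, 7.8)
  p <- pick(pc_m, pc_s)
  paco2 <- rtruncnorm(n, p$m, p$s, 15, Inf)
  p <- pick(rr_m, rr_s)
  resp_rate <- rtruncnorm(n, p$m, p$s, 6, 60)
  p <- pick(sp_m, sp_s)
  spo2 <- rtruncnorm(n, p$m, p$s, 55, 100)
  p <- pick(fi_m, fi_s)
  fio2 <- rtruncnorm(n, p$m, p$s, 0.21, 1)

  ## auxiliary guideline flags, independent of scenario except where noted
  niv_intolerant <- runif(n) < 0.05
  niv_contraindicated <- runif(n) < 0.04
  chest_trauma <- runif(n) < 0.02
  post_operative <- runif(n) < ifelse(postex, 0.35, 0.06)
  neuromuscular <- runif(n) < 0.02
  ohs <- runif(n) < 0.03
  postex_high_risk <- postex & runif(n) < 0.6
  established_pe_rf <- postex & !postex_high_risk & runif(n) < 0.5

  arf_severity <- derive_arf_severity(spo2, fio2, resp_rate)

  X <- cbind(
    age_z = (age - 62) / 16,
    cci_z = (cci - 2.5) / 2,
    sofa_z = (sofa - 2) / 2,
    ventio_z = (ventio_score - 0.3) / 0.2,
    copd_exacerbation = as.numeric(copd_ex),
    cardiogenic_edema = as.numeric(edema),
    de_novo_hypoxemic = as.numeric(denovo),
    post_extubation = as.numeric(postex),
    immunocompromised = as.numeric(immuno)
  )

  out <- .expand_coef(config$outcome_coefficients)
  eff <- .expand_coef(config$effect_coefficients)
  gu <- config$unmeasured_confounding_strength
  b0 <- logit(config$baseline_risk)
  lin_main <- b0 + config$measured_confounding_strength *
    drop(X %*% out$beta) + gu * u
  tau_x <- eff$intercept + drop(X %*% eff$beta)
  if (config$effect_type == "logistic") {
    p0 <- sigmoid(lin_main)
    p1 <- sigmoid(lin_main + tau_x)
  } else {
    p0 <- sigmoid(lin_main)
    p1 <- pmin(pmax(p0 + tau_x, 0), 1)
  }

  prop <- .expand_coef(config$propensity_coefficients)
  e <- sigmoid(prop$intercept + drop(X %*% prop$beta) + gu * u)

  list(n = n, u = u, X = X, p0 = p0, p1 = p1, propensity = e,
       statics = data.frame(
         age = age, gender = gender, cci = cci, sofa = sofa,
         ventio_score = ventio_score, chf = chf, copd = copd,
         scenario = scenario,
         copd_exacerbation = copd_ex, cardiogenic_pulmonary_edema = edema,
         de_novo_hypoxemic_rf = denovo, post_extubation = postex,
         immunocompromised = immuno,
         post_extubation_high_risk = postex_high_risk,
         established_post_extubation_rf = established_pe_rf,
         post_operative = post_operative,
         neuromuscular_disease = neuromuscular,
         obesity_hypoventilation = ohs,
         niv_intolerant = niv_intolerant,
         niv_contraindicated = niv_contraindicated,
         chest_trauma = chest_trauma,
         ph = ph, paco2 = paco2, resp_rate = resp_rate, spo2 = spo2,
         fio2 = fio2, arf_severity = arf_severity,
         stringsAsFactors = FALSE))
}

## Hourly-sampled vital/lab series anchored so that the most recent pre-T0
## value of each snapshot variable equals the stored snapshot field.
.simulate_observations <- function(enc, horizon, density) {
  n <- nrow(enc)
  vars <- c("heart_rate", "resp_rate", "sbp", "spo2",
            "ph", "paco2", "fio2", "lactate")
  sev_proxy <- (enc$sofa - 2) / 2
  anchors <- cbind(
    heart_rate = rnorm(n, 92, 12) + 5 * sev_proxy,
    resp_rate = enc$resp_rate,
    sbp = rnorm(n, 118, 16) - 5 * sev_proxy,
    spo2 = enc$spo2,
    ph = enc$ph,
    paco2 = enc$paco2,
    fio2 = enc$fio2,
    lactate = rtruncnorm(n, 1.8 + 0.5 * sev_proxy, 1.0, 0.3, Inf)
  )
  noise_sd <- c(heart_rate = 5, resp_rate = 2, sbp = 6, spo2 = 1.5,
                ph = 0.02, paco2 = 2, fio2 = 0.03, lactate = 0.3)
  lo <- c(heart_rate = 30, resp_rate = 6, sbp = 50, spo2 = 55,
          ph = 6.8, paco2 = 15, fio2 = 0.21, lactate = 0.2)
  hi <- c(heart_rate = 220, resp_rate = 60, sbp = 240, spo2 = 100,
          ph = 7.8, paco2 = 150, fio2 = 1, lactate = 20)
  snap_vars <- c("resp_rate", "spo2", "ph", "paco2", "fio2")

  V <- length(vars)
  grid <- data.table::CJ(row = seq_len(n), variable = vars, hour = 0:(horizon - 1),
                         sorted = FALSE)
  slope <- matrix(rnorm(n * V, 0, 1), n, V,
                  dimnames = list(NULL, vars))
  slope <- sweep(slope, 2, 0.02 * noise_sd[vars], `*`)
  keep <- runif(nrow(grid)) < density
  ## the last-hour observation of snapshot variables always exists and
  ## carries the snapshot value (it is the "most recent pre-T0" reading)
  is_snap0 <- grid$hour == 0 & grid$variable %in% snap_vars
  keep <- keep | is_snap0
  grid <- grid[keep]
  is_snap0 <- grid$hour == 0 & grid$variable %in% snap_vars

  hb <- grid$hour + runif(nrow(grid))
  hb[is_snap0] <- runif(sum(is_snap0), 0, 0.5)
  idx <- cbind(grid$row, match(grid$variable, vars))
  val <- anchors[idx] + slope[idx] * hb +
    rnorm(nrow(grid)) * noise_sd[grid$variable]
  val[is_snap0] <- anchors[idx][is_snap0]
  val <- pmin(pmax(val, lo[grid$variable]), hi[grid$variable])
  digits <- ifelse(grid$variable == "ph", 3,
                   ifelse(grid$variable == "fio2", 3,
                          ifelse(grid$variable == "lactate", 2, 1)))
  data.table::data.table(
    encounter_id = enc$encounter_id[grid$row],
    variable = grid$variable,
    hours_before_t0 = round(hb, 4),
    value = round(val, 3))[order(encounter_id, variable, -hours_before_t0)]
}

#' Generate a synthetic ICU cohort with counterfactual ground truth
#'
#' Simulates encounters with static features, guideline-relevant snapshot
#' fields, hourly vital/laboratory time series, a confounded binary
#' treatment (NIV vs HFNC), and binary outcomes drawn from explicit
#' potential-outcome models. Simulator ground truth (the latent confounder,
#' both potential-outcome probabilities, the true individual effect and the
#' assignment propensity) is stored in columns prefixed \code{oracle_};
#' estimator-facing code refuses to read those columns.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param timeseries logical; set \code{FALSE} to skip time-series
#'   generation when only statics/outcomes are needed (large statistical
#'   checks).
#' @return an object of class \code{icu_cohort}: a list with
#'   \code{encounters} (one row per encounter), \code{observations}
#'   (long-format \code{data.table}: encounter_id, variable,
#'   hours_before_t0, value) and the \code{config}.
#' @examples
#' coh <- generate_cohort(cohort_config(n_encounters = 50, seed = 7))
#' coh
#' @export
generate_cohort <- function(config, timeseries = TRUE) {
  if (!inherits(config, "cohort_config"))
    stopf("config must be built with cohort_config()")
  n <- config$n_encounters
  with_seed(config$seed, {
    pop <- .simulate_population(config, n)
    treatment <- ifelse(runif(n) < pop$propensity, "NIV", "HFNC")
    t1 <- treatment == "NIV"
    p_fact <- ifelse(t1, pop$p1, pop$p0)
    imv <- runif(n) < p_fact
    lp_fact <- logit(pmin(pmax(p_fact, 1e-6), 1 - 1e-6))
    lp_mort <- logit(0.30) +
      config$mortality_link_coefficient * (lp_fact - logit(config$baseline_risk)) +
      0.4 * pop$u
    mortality <- runif(n) < sigmoid(lp_mort)

    enc <- cbind(
      data.frame(encounter_id = sprintf("E%06d", seq_len(n)),
                 t0 = round(runif(n, config$horizon_hours + 1, 120), 2),
                 stringsAsFactors = FALSE),
      pop$statics,
      data.frame(treatment_received = treatment,
                 imv = imv,
                 mortality_or_hospice = mortality,
                 oracle_u = pop$u,
                 oracle_p_imv_niv = pop$p1,
                 oracle_p_imv_hfnc = pop$p0,
                 oracle_true_ite = pop$p1 - pop$p0,
                 oracle_propensity = pop$propensity,
                 stringsAsFactors = FALSE))

    obs <- if (timeseries) {
      o <- .simulate_observations(enc, config$horizon_hours, config$obs_density)
      inject_missingness(o, config$missingness_rate,
                         seed = child_seed(config$seed, 101))
    } else {
      data.table::data.table(encounter_id = character(), variable = character(),
                             hours_before_t0 = numeric(), value = numeric())
    }
    structure(list(encounters = enc, observations = obs, config = config),
              class = "icu_cohort")
  })
}

#' @export
print.icu_cohort <- function(x, ...) {
  e <- x$encounters
  cat(sprintf("Synthetic ICU cohort: %d encounters, %d observations\n",
              nrow(e), nrow(x$observations)))
  cat(sprintf("  NIV %d (%.1f%%) / HFNC %d | IMV rate %.1f%% | mortality/hospice %.1f%%\n",
              sum(e$treatment_received == "NIV"),
              100 * mean(e$treatment_received == "NIV"),
              sum(e$treatment_received == "HFNC"),
              100 * mean(e$imv), 100 * mean(e$mortality_or_hospice)))
  cat(sprintf("  mean oracle ITE %.4f (sd %.4f)\n",
              mean(e$oracle_true_ite), sd(e$oracle_true_ite)))
  invisible(x)
}

#' Population average treatment effect implied by a configuration
#'
#' High-precision Monte Carlo integral of \code{p_1(x,u) - p_0(x,u)} over
#' the covariate and latent-confounder distribution, under a fixed internal
#' oracle seed independent of the cohort seed.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n_draws Monte Carlo sample size (default 1e6).
#' @return scalar average treatment effect (NIV minus HFNC risk).
#' @export
oracle_ate <- function(config, n_draws = 1e6) {
  if (!inherits(config, "cohort_config"))
    stopf("config must be built with cohort_config()")
  with_seed(777001L, {
    pop <- .simulate_population(config, as.integer(n_draws))
    mean(pop$p1 - pop$p0)
  })
}

#' Randomly drop observations
#'
#' Each observation row is independently removed with probability
#' \code{rate}; deterministic given the seed.
#'
#' @param observations long-format observation table.
#' @param rate drop probability in \code{[0, 1)}.
#' @param seed integer seed.
#' @return the observation table with rows removed.
#' @export
inject_missingness <- function(observations, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stopf("rate must lie in [0, 1)")
  if (rate == 0) return(observations)
  with_seed(seed, {
    keep <- runif(nrow(observations)) >= rate
    observations[keep, , drop = FALSE]
  })
}
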