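## Names of the covariates entering the propensity and outcome models.
## Standardisation constants are fixed so that the oracle average treatment
## effect is a well-defined population quantity independent of the sample.
.covariate_names <- c("age_z", "cci_z", "sofa_z", "ventio_z",
                      "copd_exacerbation", "cardiogenic_edema",
                      "de_novo_hypoxemic", "post_extubation",
                      "immunocompromised")

.scenario_names <- c("copd_exacerbation", "cardiogenic_edema",
                     "de_novo_hypoxemic", "post_extubation",
                     "immunocompromised", "none")

## Columns that carry simulator ground truth. Estimator-facing code must
## never read these; the prefix is the leakage guard.
.oracle_prefix <- "oracle_"

.default_effect <- c("(Intercept)" = -0.15,
                     copd_exacerbation = -0.9,
                     cardiogenic_edema = -0.7,
                     de_novo_hypoxemic = 0.9,
                     sofa_z = 0.25)

.default_propensity <- c("(Intercept)" = -0.8,
                         copd_exacerbation = 1.4,
                         cardiogenic_edema = 0.9,
                         de_novo_hypoxemic = -1.3,
                         sofa_z = 0.3,
                         ventio_z = 0.2)

.default_outcome <- c(sofa_z = 0.8, ventio_z = 0.6, age_z = 0.3,
                      cci_z = 0.2, copd_exacerbation = 0.3,
                      de_novo_hypoxemic = 0.5)

.default_mix <- c(copd_exacerbation = 0.18, cardiogenic_edema = 0.15,
                  de_novo_hypoxemic = 0.25, post_extubation = 0.10,
                  immunocompromised = 0.07, none = 0.25)

#' Configuration for the synthetic ICU cohort simulator
#'
#' Defines the data-generating process for a cohort of ICU encounters with
#' explicit potential outcomes under NIV (treatment code 1) and HFNC
#' (treatment code 0). Potential outcomes follow a logistic model
#' \code{logit p_t(x, u) = b0 + gx'x + gu*u + t*(tau0 + tau'x)} with a
#' standard-normal unmeasured confounder \code{u} entering both the
#' propensity and the outcome; the individual treatment effect is
#' \code{p_1 - p_0}, so negative values favour NIV.
#'
#' @param n_encounters number of encounters to simulate.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @param baseline_risk probability anchoring the outcome intercept
#'   (\code{b0 = logit(baseline_risk)}); the realised invasive-ventilation
#'   rate sits a little above it because covariate noise flattens the
#'   logistic mean.
#' @param effect_coefficients named numeric vector of heterogeneous
#'   treatment-effect weights \code{tau} over the covariates listed in
#'   \code{flowcfr_covariates()}; the optional \code{"(Intercept)"} entry is
#'   the homogeneous component \code{tau0}.
#' @param measured_confounding_strength scalar multiplier on the measured
#'   covariate coefficients of the outcome model; 0 removes measured
#'   confounding of the outcome.
#' @param unmeasured_confounding_strength coefficient on the latent
#'   standard-normal \code{u} in both the propensity and the outcome model.
#' @param propensity_coefficients named numeric vector (with
#'   \code{"(Intercept)"}) for the treatment-assignment logit.
#' @param outcome_coefficients named numeric vector of outcome main effects
#'   (before scaling by \code{measured_confounding_strength}).
#' @param missingness_rate per-observation probability that a time-series
#'   measurement is dropped.
#' @param mortality_link_coefficient slope tying the mortality/hospice
#'   logit to the (centred) factual invasive-ventilation logit.
#' @param guideline_scenario_mix named proportions over the clinical
#'   scenarios that drive guideline-relevant snapshot fields; must sum to 1.
#' @param effect_type \code{"logistic"} (default, additive on the logit
#'   scale) or \code{"prob_shift"} (additive on the probability scale, in
#'   which case \code{tau0 + tau'x} is a risk difference).
#' @param horizon_hours length of the pre-decision observation window.
#' @param obs_density per-hour probability that a measurement exists before
#'   missingness injection.
#' @return an object of class \code{cohort_config}.
#' @examples
#' cfg <- cohort_config(n_encounters = 100, seed = 1)
#' cfg$guideline_scenario_mix
#' @export
cohort_config <- function(n_encounters = 5000,
                          seed = 1L,
                          baseline_risk = 0.24,
                          effect_coefficients = .default_effect,
                          measured_confounding_strength = 1,
                          unmeasured_confounding_strength = 0.6,
                          propensity_coefficients = .default_propensity,
                          outcome_coefficients = .default_outcome,
                          missingness_rate = 0.25,
                          mortality_link_coefficient = 0.8,
                          guideline_scenario_mix = .default_mix,
                          effect_type = c("logistic", "prob_shift"),
                          horizon_hours = 48,
                          obs_density = 0.95) {
  effect_type <- match.arg(effect_type)
  if (!is.numeric(n_encounters) || length(n_encounters) != 1 ||
      is.na(n_encounters) || n_encounters < 1)
    stopf("n_encounters must be a positive count, got %s",
          paste(n_encounters, collapse = ","))
  if (!is_prob(baseline_risk) || length(baseline_risk) != 1)
    stopf("baseline_risk must be a probability")
  if (!is.numeric(missingness_rate) || missingness_rate < 0 ||
      missingness_rate >= 1)
    stopf("missingness_rate must lie in [0, 1)")
  mix <- guideline_scenario_mix
  if (is.null(names(mix)) || !all(names(mix) %in% .scenario_names))
    stopf("guideline_scenario_mix names must be among: %s",
          paste(.scenario_names, collapse = ", "))
  if (any(mix < 0) || any(mix > 1))
    stopf("scenario proportions must lie in [0, 1]")
  if (abs(sum(mix) - 1) > 1e-9)
    stopf("guideline_scenario_mix must sum to 1 (got %.12f)", sum(mix))
  chk_named <- function(v, what) {
    if (length(v) && (is.null(names(v)) || any(names(v) == "")))
      stopf("%s must be a named numeric vector", what)
    bad <- setdiff(names(v), c("(Intercept)", .covariate_names))
    if (length(bad))
      stopf("%s references unknown covariates: %s", what,
            paste(bad, collapse = ", "))
    v
  }
  structure(list(
    n_encounters = as.integer(n_encounters),
    seed = as.integer(seed),
    baseline_risk = baseline_risk,
    effect_coefficients = chk_named(effect_coefficients, "effect_coefficients"),
    measured_confounding_strength = measured_confounding_strength,
    unmeasured_confounding_strength = unmeasured_confounding_strength,
    propensity_coefficients = chk_named(propensity_coefficients,
                                        "propensity_coefficients"),
    outcome_coefficients = chk_named(outcome_coefficients,
                                     "outcome_coefficients"),
    missingness_rate = missingness_rate,
    mortality_link_coefficient = mortality_link_coefficient,
    guideline_scenario_mix = mix,
    effect_type = effect_type,
    horizon_hours = as.integer(horizon_hours),
    obs_density = obs_density
  ), class = "cohort_config")
}

#' Covariate names of the simulator's structural models
#'
#' @return character vector of covariate names usable in
#'   \code{\link{cohort_config}} coefficient maps.
#' @export
flowcfr_covariates <- function() .covariate_names

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic ICU cohort configuration\n")
  cat(sprintf("  encounters: %d  seed: %d  baseline risk: %.3f\n",
              x$n_encounters, x$seed, x$baseline_risk))
  cat(sprintf("  effect type: %s  unmeasured confounding: %.2f\n",
              x$effect_type, x$unmeasured_confounding_strength))
  cat("  scenario mix:",
      paste(sprintf("%s=%.2f", names(x$guideline_scenario_mix),
                    x$guideline_scenario_mix), collapse = " "), "\n")
  invisible(x)
}

## Expand a named coefficient map to (intercept, dense vector over
## .covariate_names).
.expand_coef <- function(coef) {
  b0 <- unname(coef["(Intercept)"])
  if (is.na(b0)) b0 <- 0
  v <- setNames(numeric(length(.covariate_names)), .covariate_names)
  keep <- setdiff(names(coef), "(Intercept)")
  v[keep] <- coef[keep]
  list(intercept = b0, beta = v)
}
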