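# Shared fixtures, built in code at test time. Expensive objects are cached
# per session in this environment so several test files can reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_cohort <- function(n = 200, seed = 42, timeseries = TRUE, ...) {
  generate_cohort(cohort_config(n_encounters = n, seed = seed, ...),
                  timeseries = timeseries)
}

## default study-conditions cohort used by the estimator property suite
default_cohort_5000 <- function() {
  cached("coh5000", generate_cohort(cohort_config(n_encounters = 5000,
                                                  seed = 11)))
}

default_features_5000 <- function() {
  cached("fs5000", assemble_features(default_cohort_5000()))
}

default_fit_5000 <- function() {
  cached("fit5000", {
    coh <- default_cohort_5000()
    fs <- default_features_5000()
    cfrflow(fs$features,
            coh$encounters$treatment_received,
            coh$encounters$imv,
            cfrflow_config(seed = 4))
  })
}

## feature matrix straight from encounter statics (no time series), for
## estimator tests that do not exercise the feature pipeline
static_features <- function(enc) {
  cbind(age = enc$age, gender = as.numeric(enc$gender == "M"),
        cci = enc$cci, sofa = enc$sofa, ventio = enc$ventio_score,
        copd_ex = as.numeric(enc$copd_exacerbation),
        edema = as.numeric(enc$cardiogenic_pulmonary_edema),
        denovo = as.numeric(enc$de_novo_hypoxemic_rf),
        postex = as.numeric(enc$post_extubation),
        immuno = as.numeric(enc$immunocompromised))
}

random_snapshot <- function() {
  clinical_snapshot(
    ph = runif(1, 7.05, 7.65), paco2 = runif(1, 20, 90),
    resp_rate = runif(1, 8, 45), spo2 = runif(1, 70, 100),
    fio2 = runif(1, 0.21, 1),
    copd_exacerbation = runif(1) < 0.3,
    cardiogenic_pulmonary_edema = runif(1) < 0.15,
    neuromuscular_disease = runif(1) < 0.05,
    obesity_hypoventilation = runif(1) < 0.05,
    post_extubation = runif(1) < 0.15,
    post_extubation_high_risk = runif(1) < 0.1,
    established_post_extubation_rf = runif(1) < 0.05,
    post_operative = runif(1) < 0.1,
    immunocompromised = runif(1) < 0.1,
    de_novo_hypoxemic_rf = runif(1) < 0.25,
    niv_intolerant = runif(1) < 0.1,
    niv_contraindicated = runif(1) < 0.08,
    chest_trauma = runif(1) < 0.05)
}
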