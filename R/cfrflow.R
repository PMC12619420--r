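#' Fit the full three-stage counterfactual flow estimator
#'
#' Trains, in order and each frozen before the next: the balanced
#' representation and outcome heads (stage 0), the conditional outcome flow
#' (stage 1) and the interventional latent flow (stage 2).
#'
#' @param features numeric matrix (encounters x features), typically from
#'   \code{\link{assemble_features}}.
#' @param treatment 0/1 vector (1 = NIV) or a character vector of
#'   "NIV"/"HFNC".
#' @param outcome 0/1 or logical vector (invasive ventilation).
#' @param config a \code{\link{cfrflow_config}}.
#' @param val optional validation list for stage-0 early stopping.
#' @return an object of class \code{cfrflow}.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_encounters = 400, seed = 3))
#' fs <- assemble_features(coh)
#' fit <- cfrflow(fs$features, coh$encounters$treatment_received,
#'                coh$encounters$imv,
#'                cfrflow_config(max_epochs = 5, seed = 3))
#' head(predict(fit, fs$features))
#' }
#' @export
cfrflow <- function(features, treatment, outcome, config = cfrflow_config(),
                    val = NULL) {
  if (is.character(treatment) || is.factor(treatment))
    treatment <- as.numeric(as.character(treatment) == "NIV")
  outcome <- as.numeric(outcome)
  s0 <- train_stage0(features, treatment, outcome, config, val)
  R <- encode_features(s0, features)
  p_fact <- ifelse(treatment == 1, head_risk(s0, R, 1), head_risk(s0, R, 0))
  s1 <- train_stage1(R, treatment, outcome, config, p_fact)
  eps <- stage1_residuals(s1, R, treatment, outcome, p_fact)
  s2 <- train_stage2(R, eps, treatment, config)
  structure(list(stage0 = s0, stage1 = s1, stage2 = s2, config = config,
                 feature_names = colnames(features)),
            class = "cfrflow")
}

#' @export
print.cfrflow <- function(x, ...) {
  cat("Counterfactual flow estimator (3 stages)\n")
  cat(sprintf("  features: %d | rep_dim: %d | stage0 best epoch %d (val loss %.4f)\n",
              length(x$feature_names), x$config$rep_dim,
              x$stage0$best_epoch, x$stage0$best_val_loss))
  cat(sprintf("  flow depths %d/%d | inference draws %d | band %.4g\n",
              x$config$flow_depth_stage1, x$config$flow_depth_stage2,
              x$config$n_draws, x$config$ite_band))
  invisible(x)
}

#' Potential-outcome risks under both arms
#'
#' For each encounter, draws \code{n_draws} latents from the stage-2
#' interventional flow conditioned on the representation, maps them through
#' the stage-1 flow under each counterfactual arm, and averages
#' \code{sigmoid} of the resulting scores. Both arms share the same latent
#' draws (common random numbers).
#'
#' @param features feature matrix.
#' @param model a fitted \code{\link{cfrflow}}.
#' @param n_draws latent draws per encounter (default from the config).
#' @param seed seed for the base draws.
#' @param use_stage2 set FALSE to sample the stage-1 base directly
#'   (no unmeasured-confounding adjustment).
#' @return matrix with columns \code{p_imv_niv}, \code{p_imv_hfnc}.
#' @export
predict_potential <- function(features, model, n_draws = NULL, seed = 1L,
                              use_stage2 = TRUE) {
  if (!inherits(model, "cfrflow")) stopf("model must be a fitted cfrflow")
  n_draws <- as.integer(n_draws %||% model$config$n_draws)
  X <- as.matrix(features)
  n <- nrow(X)
  R <- encode_features(model$stage0, X)
  base <- with_seed(seed, matrix(rnorm(n * n_draws), n, n_draws))

  p1 <- numeric(n); p0 <- numeric(n)
  chunk <- max(1L, floor(2e5 / n_draws))
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    m <- length(ii)
    Rrep <- R[rep(ii, each = n_draws), , drop = FALSE]
    eps <- as.vector(t(base[ii, , drop = FALSE]))
    z <- if (use_stage2) flow_generate(model$stage2$flow, eps, Rrep) else eps
    s_niv <- flow_generate(model$stage1$flow, z,
                           .stage1_context(Rrep, rep(1, m * n_draws)))
    s_hfnc <- flow_generate(model$stage1$flow, z,
                            .stage1_context(Rrep, rep(0, m * n_draws)))
    p1[ii] <- rowMeans(matrix(sigmoid(s_niv), m, n_draws, byrow = TRUE))
    p0[ii] <- rowMeans(matrix(sigmoid(s_hfnc), m, n_draws, byrow = TRUE))
  }
  cbind(p_imv_niv = p1, p_imv_hfnc = p0)
}

#' Banded modality label from potential-outcome risks
#'
#' NIV when the risk difference (NIV minus HFNC) is below \code{-band},
#' HFNC when above \code{band}, Indifferent otherwise; band endpoints are
#' Indifferent because the preference inequalities are strict.
#'
#' @param p_imv_niv,p_imv_hfnc risk probabilities.
#' @param band indifference half-width (default 0.001).
#' @return character vector in \{"NIV", "HFNC", "Indifferent"\}.
#' @export
classify_ite <- function(p_imv_niv, p_imv_hfnc, band = 0.001) {
  if (!is_prob(p_imv_niv) || !is_prob(p_imv_hfnc))
    stopf("risks must be probabilities in [0, 1]")
  ite <- p_imv_niv - p_imv_hfnc
  ## numerical slack so risks whose difference is the band value up to
  ## floating-point error land on the (Indifferent) endpoint
  eps <- band * 1e-6
  ifelse(ite < -(band + eps), "NIV",
         ifelse(ite > band + eps, "HFNC", "Indifferent"))
}

#' Individual treatment-effect estimates for a cohort
#'
#' @param object a fitted \code{\link{cfrflow}}.
#' @param features feature matrix (rownames are encounter ids).
#' @param n_draws,seed passed to \code{\link{predict_potential}}.
#' @param ... unused.
#' @return data.frame: encounter_id, p_imv_niv, p_imv_hfnc, ite, modality,
#'   n_draws_used.
#' @export
predict.cfrflow <- function(object, features, n_draws = NULL, seed = 1L,
                            ...) {
  n_draws <- as.integer(n_draws %||% object$config$n_draws)
  P <- predict_potential(features, object, n_draws, seed)
  ite <- P[, "p_imv_niv"] - P[, "p_imv_hfnc"]
  data.frame(encounter_id = rownames(features) %||%
               as.character(seq_len(nrow(P))),
             p_imv_niv = P[, "p_imv_niv"], p_imv_hfnc = P[, "p_imv_hfnc"],
             ite = ite,
             modality = classify_ite(P[, "p_imv_niv"], P[, "p_imv_hfnc"],
                                     object$config$ite_band),
             n_draws_used = n_draws,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Constant plug-in effect estimate with no balancing
#'
#' The naive per-arm outcome-rate difference (NIV rate minus HFNC rate),
#' assigned to every encounter. The comparison baseline for the estimator's
#' heterogeneous effect recovery; confounded by design on observational
#' cohorts.
#'
#' @param treatment 0/1 or "NIV"/"HFNC" vector.
#' @param outcome 0/1 vector.
#' @return scalar risk difference.
#' @export
naive_plugin_ite <- function(treatment, outcome) {
  if (is.character(treatment) || is.factor(treatment))
    treatment <- as.numeric(as.character(treatment) == "NIV")
  outcome <- as.numeric(outcome)
  mean(outcome[treatment == 1]) - mean(outcome[treatment == 0])
}

#' Root-mean-squared error of individual effect estimates
#'
#' @param estimated,true effect vectors (recycled if scalar).
#' @return scalar PEHE (precision in estimating heterogeneous effects).
#' @export
pehe <- function(estimated, true) sqrt(mean((estimated - true)^2))

#' Fraction of encounters whose estimated effect sign matches the truth
#'
#' @param estimated,true effect vectors.
#' @return proportion in [0, 1].
#' @export
sign_agreement <- function(estimated, true) mean(sign(estimated) == sign(true))
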