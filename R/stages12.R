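## Stages 1 and 2: conditional-flow outcome modelling and the
## interventional latent adjustment.
##
## Stage 1 models the distribution of a latent outcome score s given the
## representation and the treatment arm. The score is built on the logit
## scale from the stage-0 head risk and the outcome residual,
##   s_i = logit(p_hat_i) + spread * (y_i - p_hat_i),
## a continuous construction whose sigmoid-average approximately preserves
## the head risk while giving the flow a non-degenerate target.
##
## Stage 2 models the pooled (treatment-marginalised) distribution of the
## stage-1 base residuals given the representation alone. At inference,
## draws from stage 2 replace the standard-normal base of stage 1, so both
## counterfactual conditionings are evaluated under a shared,
## treatment-independent latent distribution.

## stage-1 conditioning: representation, arm indicator and their
## interaction, so arm-specific (heterogeneous) shifts stay representable
## under the flow's context-linear parameterisation
.stage1_context <- function(R, t_arm) cbind(R, t = t_arm, R * t_arm)

.latent_score <- function(risk, outcome, spread) {
  risk <- pmin(pmax(risk, 1e-6), 1 - 1e-6)
  logit(risk) + spread * (outcome - risk)
}

#' Train the conditional outcome flow (stage 1)
#'
#' @param representations matrix from \code{\link{encode_features}} (the
#'   encoder is frozen).
#' @param treatment 0/1 vector.
#' @param outcome 0/1 vector.
#' @param config a \code{\link{cfrflow_config}}.
#' @param factual_risk head risk under the received arm (from
#'   \code{\link{head_risk}}); required to build the latent score.
#' @return an object of class \code{cfr_stage1} holding the fitted flow.
#' @export
train_stage1 <- function(representations, treatment, outcome, config,
                         factual_risk) {
  R <- as.matrix(representations)
  t_arm <- as.numeric(treatment)
  y <- as.numeric(outcome)
  if (sd(y) < 1e-12) stopf("degenerate (constant) outcome: nothing to model")
  s <- .latent_score(factual_risk, y, config$score_spread)
  C <- .stage1_context(R, t_arm)
  fl <- cond_flow(ncol(C), config$flow_depth_stage1)
  fl <- flow_fit(fl, s, C, lr = config$flow_lr,
                 max_epochs = config$max_epochs * 5,
                 patience = config$patience,
                 seed = child_seed(config$seed, 31))
  structure(list(flow = fl, score_spread = config$score_spread,
                 training_log = attr(fl, "training_log")),
            class = "cfr_stage1")
}

#' Train the interventional latent flow (stage 2)
#'
#' @param representations representation matrix.
#' @param stage1_latents base residuals of the stage-1 flow at the factual
#'   (representation, treatment) pairs.
#' @param treatment 0/1 vector (unused by the pooled formulation; kept for
#'   the stage interface).
#' @param config a \code{\link{cfrflow_config}}.
#' @return an object of class \code{cfr_stage2}.
#' @export
train_stage2 <- function(representations, stage1_latents, treatment,
                         config) {
  R <- as.matrix(representations)
  fl <- cond_flow(ncol(R), config$flow_depth_stage2)
  fl <- flow_fit(fl, stage1_latents, R, lr = config$flow_lr,
                 max_epochs = config$max_epochs * 5,
                 patience = config$patience,
                 seed = child_seed(config$seed, 37))
  structure(list(flow = fl, training_log = attr(fl, "training_log")),
            class = "cfr_stage2")
}

#' Stage-1 base residuals at the factual pairs
#'
#' @param stage1 a fitted \code{cfr_stage1}.
#' @param representations representation matrix.
#' @param treatment 0/1 vector.
#' @param outcome 0/1 vector.
#' @param factual_risk factual head risk.
#' @return residual vector (the stage-2 training target).
#' @export
stage1_residuals <- function(stage1, representations, treatment, outcome,
                             factual_risk) {
  s <- .latent_score(factual_risk, as.numeric(outcome), stage1$score_spread)
  C <- .stage1_context(as.matrix(representations), as.numeric(treatment))
  flow_normalize(stage1$flow, s, C)$eps
}
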