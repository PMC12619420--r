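#' Configuration of the counterfactual flow estimator
#'
#' Hyperparameters of the three-stage estimator: balanced representation
#' learning (stage 0), a conditional outcome flow (stage 1) and an
#' interventional latent flow (stage 2).
#'
#' @param rep_dim representation dimension.
#' @param encoder_layers integer vector of encoder hidden-layer widths.
#' @param head_layers integer vector of outcome-head hidden-layer widths.
#' @param flow_depth_stage1,flow_depth_stage2 flow depths.
#' @param alpha_ipm weight of the between-arm Wasserstein balancing penalty
#'   (0 disables balancing).
#' @param learning_rate Adam learning rate (stage 0).
#' @param weight_decay L2 penalty on weights.
#' @param dropout hidden-unit dropout rate in \code{[0, 1)}.
#' @param batch_size minibatch size (stage 0).
#' @param max_epochs epoch cap per stage.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param n_draws latent draws per encounter at inference (default 100).
#' @param ite_band half-width of the indifference band on the individual
#'   treatment effect: NIV when ITE < -band, HFNC when ITE > band,
#'   Indifferent otherwise (default 0.001, i.e. a tenth of a percentage
#'   point of risk).
#' @param sinkhorn_epsilon entropic regularisation of the balancing metric.
#' @param score_spread spread of the latent outcome-score construction
#'   (see the stage 1 documentation).
#' @param flow_lr learning rate for the flow stages.
#' @param seed integer seed governing initialisation, batching, dropout
#'   and inference draws.
#' @return an object of class \code{cfrflow_config}.
#' @export
cfrflow_config <- function(rep_dim = 24,
                           encoder_layers = c(48),
                           head_layers = c(16),
                           flow_depth_stage1 = 4,
                           flow_depth_stage2 = 4,
                           alpha_ipm = 0.3,
                           learning_rate = 1e-3,
                           weight_decay = 1e-4,
                           dropout = 0.1,
                           batch_size = 256,
                           max_epochs = 300,
                           patience = 30,
                           n_draws = 100,
                           ite_band = 0.001,
                           sinkhorn_epsilon = 0.1,
                           score_spread = 0.5,
                           flow_lr = 0.05,
                           seed = 1L) {
  if (n_draws < 1) stopf("n_draws must be >= 1")
  if (ite_band <= 0) stopf("ite_band must be positive")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  if (alpha_ipm < 0) stopf("alpha_ipm must be non-negative")
  structure(list(rep_dim = as.integer(rep_dim),
                 encoder_layers = as.integer(encoder_layers),
                 head_layers = as.integer(head_layers),
                 flow_depth_stage1 = as.integer(flow_depth_stage1),
                 flow_depth_stage2 = as.integer(flow_depth_stage2),
                 alpha_ipm = alpha_ipm, learning_rate = learning_rate,
                 weight_decay = weight_decay, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_draws = as.integer(n_draws), ite_band = ite_band,
                 sinkhorn_epsilon = sinkhorn_epsilon,
                 score_spread = score_spread, flow_lr = flow_lr,
                 seed = as.integer(seed)),
            class = "cfrflow_config")
}

#' @export
print.cfrflow_config <- function(x, ...) {
  cat("Counterfactual flow estimator configuration\n")
  cat(sprintf("  rep_dim %d | encoder [%s] | heads [%s] | flows %d/%d deep\n",
              x$rep_dim, paste(x$encoder_layers, collapse = ","),
              paste(x$head_layers, collapse = ","),
              x$flow_depth_stage1, x$flow_depth_stage2))
  cat(sprintf("  alpha_ipm %.3g | lr %.3g | batch %d | draws %d | band %.4g\n",
              x$alpha_ipm, x$learning_rate, x$batch_size, x$n_draws,
              x$ite_band))
  invisible(x)
}

#' Split a cohort into training and validation parts
#'
#' Disjoint, exhaustive, deterministic given the seed; the training part
#' holds \code{floor(train_fraction * n)} encounters.
#'
#' @param cohort an \code{icu_cohort}, or any data.frame with an
#'   \code{encounter_id} column.
#' @param train_fraction default 0.8.
#' @param seed integer seed.
#' @return list with \code{train_ids} and \code{val_ids}.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L) {
  ids <- if (inherits(cohort, "icu_cohort")) cohort$encounters$encounter_id
         else cohort$encounter_id
  n <- length(ids)
  if (n < 5) stopf("need at least 5 encounters to split")
  n_tr <- floor(train_fraction * n)
  tr <- with_seed(seed, sample(ids, n_tr))
  list(train_ids = tr, val_ids = setdiff(ids, tr))
}
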