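#' Discrimination metrics for risk predictions
#'
#' Area under the ROC curve (via \pkg{pROC}) and the area under the
#' precision-recall curve computed as average precision (step-function
#' integral of precision over recall at each positive threshold).
#'
#' @param predicted numeric risk scores.
#' @param outcomes 0/1 or logical outcomes.
#' @return list with \code{auc} and \code{pr_auc}.
#' @export
evaluate_discrimination <- function(predicted, outcomes) {
  y <- as.numeric(outcomes)
  if (length(unique(y)) < 2) stopf("outcomes must contain both classes")
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = predicted,
                                        quiet = TRUE, direction = "<",
                                        levels = c(0, 1))))
  ord <- order(predicted, decreasing = TRUE)
  ys <- y[ord]
  tp <- cumsum(ys)
  prec <- tp / seq_along(ys)
  ## average precision over positives, merging tied scores at the last
  ## index of each tie block
  ps <- predicted[ord]
  last_of_tie <- c(ps[-length(ps)] != ps[-1], TRUE)
  npos <- sum(ys)
  rec <- tp / npos
  idx <- which(last_of_tie)
  r_prev <- c(0, rec[idx][-length(idx)])
  pr_auc <- sum((rec[idx] - r_prev) * prec[idx])
  list(auc = auc, pr_auc = pr_auc)
}
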