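## Stage 0: balanced representation learning (counterfactual regression).
## A shared encoder maps covariates to a representation; two heads predict
## factual risk per treatment arm; the loss adds an integral probability
## metric (Sinkhorn transport value) between the treated and control
## representation clouds, which discourages the encoder from retaining
## treatment-predictive (confounding) directions.

#' Train the balanced-representation stage
#'
#' @param features numeric matrix (encounters x features).
#' @param treatment 0/1 vector (1 = NIV, 0 = HFNC).
#' @param outcome 0/1 vector (1 = invasive ventilation).
#' @param config a \code{\link{cfrflow_config}}.
#' @param val optional list(features, treatment, outcome) used for early
#'   stopping; a seeded internal 20\% carve-out is used when NULL.
#' @return an object of class \code{cfr_stage0}: encoder, heads,
#'   standardisation constants and a per-epoch training log (factual loss,
#'   balancing penalty, validation loss).
#' @export
train_stage0 <- function(features, treatment, outcome, config, val = NULL) {
  X <- as.matrix(features)
  t_arm <- as.numeric(treatment)
  y <- as.numeric(outcome)
  if (!all(t_arm %in% c(0, 1))) stopf("treatment must be binary 0/1")
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  if (any(!is.finite(X))) stopf("features must be finite")

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  if (is.null(val)) {
    idx <- with_seed(child_seed(config$seed, 7), {
      n <- nrow(Xs); sample(n, max(1L, floor(0.2 * n)))
    })
    val <- list(features = Xs[idx, , drop = FALSE], treatment = t_arm[idx],
                outcome = y[idx], standardized = TRUE)
    keep <- setdiff(seq_len(nrow(Xs)), idx)
    Xs <- Xs[keep, , drop = FALSE]; t_arm <- t_arm[keep]; y <- y[keep]
  }
  Xv <- as.matrix(val$features)
  if (is.null(val$standardized) || !isTRUE(val$standardized))
    Xv <- sweep(sweep(Xv, 2, ctr), 2, scl, `/`)
  tv <- as.numeric(val$treatment); yv <- as.numeric(val$outcome)

  n <- nrow(Xs); d <- ncol(Xs)
  with_seed(config$seed, {
    enc <- mlp_init(c(d, config$encoder_layers, config$rep_dim))
    h0 <- mlp_init(c(config$rep_dim, config$head_layers, 1L))
    h1 <- mlp_init(c(config$rep_dim, config$head_layers, 1L))
    st_enc <- adam_init(enc); st_h0 <- adam_init(h0); st_h1 <- adam_init(h1)

    fwd_val <- function(enc, h0, h1) {
      R <- mlp_forward(enc, Xv)$out
      z <- numeric(length(yv))
      i1 <- tv == 1
      if (any(i1)) z[i1] <- mlp_forward(h1, R[i1, , drop = FALSE])$out
      if (any(!i1)) z[!i1] <- mlp_forward(h0, R[!i1, , drop = FALSE])$out
      bce_loss(sigmoid(z), yv)
    }

    best <- list(val = Inf, enc = enc, h0 = h0, h1 = h1, epoch = 0L)
    log_df <- data.frame(epoch = integer(), factual_loss = numeric(),
                         ipm = numeric(), val_loss = numeric())
    wait <- 0L
    nb <- max(1L, ceiling(n / config$batch_size))
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_ipm <- 0
      for (b in seq_len(nb)) {
        idx <- ord[seq.int((b - 1L) * config$batch_size + 1L,
                           min(b * config$batch_size, n))]
        Xb <- Xs[idx, , drop = FALSE]
        tb <- t_arm[idx]; yb <- y[idx]; m <- length(idx)

        dm <- NULL
        if (config$dropout > 0) {
          dm <- lapply(config$encoder_layers, function(w)
            matrix(rbinom(m * w, 1, 1 - config$dropout) /
                     (1 - config$dropout), m, w))
        }
        ce <- mlp_forward(enc, Xb, dm)
        R <- ce$out
        i1 <- tb == 1
        dR <- matrix(0, m, config$rep_dim)
        loss <- 0
        gr_h0 <- NULL; gr_h1 <- NULL
        if (any(i1)) {
          c1 <- mlp_forward(h1, R[i1, , drop = FALSE])
          p1 <- sigmoid(drop(c1$out))
          loss <- loss + sum(-(yb[i1] * log(pmax(p1, 1e-12)) +
                                 (1 - yb[i1]) * log(pmax(1 - p1, 1e-12))))
          dz <- matrix((p1 - yb[i1]) / m, ncol = 1)
          gr_h1 <- mlp_backward(h1, c1, dz)
          dR[i1, ] <- dR[i1, ] + gr_h1$dX
        }
        if (any(!i1)) {
          c0 <- mlp_forward(h0, R[!i1, , drop = FALSE])
          p0 <- sigmoid(drop(c0$out))
          loss <- loss + sum(-(yb[!i1] * log(pmax(p0, 1e-12)) +
                                 (1 - yb[!i1]) * log(pmax(1 - p0, 1e-12))))
          dz <- matrix((p0 - yb[!i1]) / m, ncol = 1)
          gr_h0 <- mlp_backward(h0, c0, dz)
          dR[!i1, ] <- dR[!i1, ] + gr_h0$dX
        }
        loss <- loss / m

        ipm_val <- 0
        if (config$alpha_ipm > 0 && sum(i1) >= 2 && sum(!i1) >= 2) {
          sk <- sinkhorn_plan(R[i1, , drop = FALSE], R[!i1, , drop = FALSE],
                              epsilon = config$sinkhorn_epsilon, n_iter = 50)
          ipm_val <- sk$value
          Dsafe <- pmax(sk$cost, 1e-9)
          W <- sk$plan / Dsafe
          A1 <- R[i1, , drop = FALSE]; A0 <- R[!i1, , drop = FALSE]
          gA1 <- rowSums(W) * A1 - W %*% A0
          gA0 <- colSums(W) * A0 - t(W) %*% A1
          dR[i1, ] <- dR[i1, ] + config$alpha_ipm * gA1
          dR[!i1, ] <- dR[!i1, ] + config$alpha_ipm * gA0
        }

        gr_enc <- mlp_backward(enc, ce, dR)
        up <- adam_step(enc, gr_enc, st_enc, config$learning_rate,
                        config$weight_decay)
        enc <- up$net; st_enc <- up$state
        if (!is.null(gr_h1)) {
          up <- adam_step(h1, gr_h1, st_h1, config$learning_rate,
                          config$weight_decay)
          h1 <- up$net; st_h1 <- up$state
        }
        if (!is.null(gr_h0)) {
          up <- adam_step(h0, gr_h0, st_h0, config$learning_rate,
                          config$weight_decay)
          h0 <- up$net; st_h0 <- up$state
        }
        ep_loss <- ep_loss + loss; ep_ipm <- ep_ipm + ipm_val
      }
      vl <- fwd_val(enc, h0, h1)
      log_df <- rbind(log_df, data.frame(
        epoch = ep, factual_loss = ep_loss / nb, ipm = ep_ipm / nb,
        val_loss = vl))
      if (vl < best$val - 1e-6) {
        best <- list(val = vl, enc = enc, h0 = h0, h1 = h1, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(encoder = best$enc, head0 = best$h0, head1 = best$h1,
                   center = ctr, scale = scl, config = config,
                   training_log = log_df, best_epoch = best$epoch,
                   best_val_loss = best$val),
              class = "cfr_stage0")
  })
}

#' Encode features into the balanced representation
#'
#' @param stage0 a fitted \code{cfr_stage0}.
#' @param features feature matrix on the original scale.
#' @return representation matrix (encounters x rep_dim).
#' @export
encode_features <- function(stage0, features) {
  Xs <- sweep(sweep(as.matrix(features), 2, stage0$center), 2,
              stage0$scale, `/`)
  mlp_forward(stage0$encoder, Xs)$out
}

#' Factual risk from the outcome heads
#'
#' @param stage0 a fitted \code{cfr_stage0}.
#' @param representations representation matrix.
#' @param arm 0 (HFNC) or 1 (NIV).
#' @return risk probabilities.
#' @export
head_risk <- function(stage0, representations, arm) {
  net <- if (arm == 1) stage0$head1 else stage0$head0
  sigmoid(drop(mlp_forward(net, as.matrix(representations))$out))
}
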