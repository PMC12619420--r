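test_that("network gradients match finite differences", {
  set.seed(31)
  net <- flowcfr:::mlp_init(c(3, 4, 1))
  X <- matrix(rnorm(18), 6, 3)
  y <- rbinom(6, 1, 0.5)
  loss_of <- function(net) {
    p <- plogis(drop(flowcfr:::mlp_forward(net, X)$out))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  cache <- flowcfr:::mlp_forward(net, X)
  p <- plogis(drop(cache$out))
  gr <- flowcfr:::mlp_backward(net, cache, matrix((p - y) / 6, ncol = 1))
  h <- 1e-6
  for (l in 1:2) {
    for (k in seq_along(net$W[[l]])) {
      np <- net; np$W[[l]][k] <- np$W[[l]][k] + h
      nm <- net; nm$W[[l]][k] <- nm$W[[l]][k] - h
      expect_equal(gr$gW[[l]][k], (loss_of(np) - loss_of(nm)) / (2 * h),
                   tolerance = 1e-4)
    }
    for (k in seq_along(net$b[[l]])) {
      np <- net; np$b[[l]][k] <- np$b[[l]][k] + h
      nm <- net; nm$b[[l]][k] <- nm$b[[l]][k] - h
      expect_equal(gr$gb[[l]][k], (loss_of(np) - loss_of(nm)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("training is reproducible under a fixed seed", {
  coh <- small_cohort(n = 150, seed = 2, timeseries = FALSE)
  X <- static_features(coh$encounters)
  tt <- as.numeric(coh$encounters$treatment_received == "NIV")
  y <- as.numeric(coh$encounters$imv)
  cfg <- cfrflow_config(seed = 9, max_epochs = 6, patience = 3)
  s1 <- train_stage0(X, tt, y, cfg)
  s2 <- train_stage0(X, tt, y, cfg)
  expect_identical(s1$training_log, s2$training_log)
  expect_identical(s1$encoder$W, s2$encoder$W)
  expect_error(train_stage0(X, tt + 0.5, y, cfg), "binary")
})

test_that("with no balancing penalty the wrapper equals a plain two-head net", {
  coh <- small_cohort(n = 200, seed = 6, timeseries = FALSE)
  X <- static_features(coh$encounters)
  tt <- as.numeric(coh$encounters$treatment_received == "NIV")
  y <- as.numeric(coh$encounters$imv)
  ntr <- 160
  val <- list(features = X[161:200, ], treatment = tt[161:200],
              outcome = y[161:200])
  Xtr <- X[1:ntr, ]; ttr <- tt[1:ntr]; ytr <- y[1:ntr]
  cfg <- cfrflow_config(seed = 13, alpha_ipm = 0, dropout = 0,
                        max_epochs = 8, patience = 8, batch_size = 64)
  s0 <- train_stage0(Xtr, ttr, ytr, cfg, val = val)
  expect_true(all(s0$training_log$ipm == 0))

  ## independent plain trainer with the identical seed and schedule
  ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, sd); scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(Xtr, 2, ctr), 2, scl, `/`)
  Xv <- sweep(sweep(as.matrix(val$features), 2, ctr), 2, scl, `/`)
  logs <- withr::with_seed(cfg$seed, {
    enc <- flowcfr:::mlp_init(c(ncol(Xs), cfg$encoder_layers, cfg$rep_dim))
    h0 <- flowcfr:::mlp_init(c(cfg$rep_dim, cfg$head_layers, 1L))
    h1 <- flowcfr:::mlp_init(c(cfg$rep_dim, cfg$head_layers, 1L))
    se <- flowcfr:::adam_init(enc); s_h0 <- flowcfr:::adam_init(h0)
    s_h1 <- flowcfr:::adam_init(h1)
    vl <- numeric(0)
    nb <- ceiling(ntr / cfg$batch_size)
    for (ep in 1:8) {
      ord <- sample(ntr)
      for (b in seq_len(nb)) {
        idx <- ord[seq.int((b - 1) * cfg$batch_size + 1,
                           min(b * cfg$batch_size, ntr))]
        m <- length(idx)
        ce <- flowcfr:::mlp_forward(enc, Xs[idx, , drop = FALSE])
        R <- ce$out
        dR <- matrix(0, m, cfg$rep_dim)
        i1 <- ttr[idx] == 1
        g1 <- NULL; g0 <- NULL
        if (any(i1)) {
          c1 <- flowcfr:::mlp_forward(h1, R[i1, , drop = FALSE])
          p1 <- plogis(drop(c1$out))
          g1 <- flowcfr:::mlp_backward(h1, c1,
                                       matrix((p1 - ytr[idx][i1]) / m, ncol = 1))
          dR[i1, ] <- g1$dX
        }
        if (any(!i1)) {
          c0 <- flowcfr:::mlp_forward(h0, R[!i1, , drop = FALSE])
          p0 <- plogis(drop(c0$out))
          g0 <- flowcfr:::mlp_backward(h0, c0,
                                       matrix((p0 - ytr[idx][!i1]) / m, ncol = 1))
          dR[!i1, ] <- g0$dX
        }
        ge <- flowcfr:::mlp_backward(enc, ce, dR)
        up <- flowcfr:::adam_step(enc, ge, se, cfg$learning_rate,
                                  cfg$weight_decay)
        enc <- up$net; se <- up$state
        if (!is.null(g1)) {
          up <- flowcfr:::adam_step(h1, g1, s_h1, cfg$learning_rate,
                                    cfg$weight_decay)
          h1 <- up$net; s_h1 <- up$state
        }
        if (!is.null(g0)) {
          up <- flowcfr:::adam_step(h0, g0, s_h0, cfg$learning_rate,
                                    cfg$weight_decay)
          h0 <- up$net; s_h0 <- up$state
        }
      }
      Rv <- flowcfr:::mlp_forward(enc, Xv)$out
      z <- numeric(nrow(Xv))
      iv <- val$treatment == 1
      if (any(iv)) z[iv] <- flowcfr:::mlp_forward(h1, Rv[iv, , drop = FALSE])$out
      if (any(!iv)) z[!iv] <- flowcfr:::mlp_forward(h0, Rv[!iv, , drop = FALSE])$out
      vl <- c(vl, flowcfr:::bce_loss(plogis(z), val$outcome))
    }
    vl
  })
  expect_equal(s0$training_log$val_loss, logs, tolerance = 1e-10)
})

test_that("the balancing penalty shrinks the between-arm representation gap", {
  coh <- small_cohort(n = 600, seed = 19, timeseries = FALSE)
  X <- static_features(coh$encounters)
  tt <- as.numeric(coh$encounters$treatment_received == "NIV")
  y <- as.numeric(coh$encounters$imv)
  ipm_of <- function(alpha) {
    cfg <- cfrflow_config(seed = 3, alpha_ipm = alpha, max_epochs = 25,
                          patience = 25, dropout = 0)
    s0 <- train_stage0(X, tt, y, cfg)
    R <- encode_features(s0, X)
    wasserstein_ipm(R[tt == 1, ], R[tt == 0, ], epsilon = 0.1)
  }
  expect_lt(ipm_of(10), ipm_of(0))
})
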