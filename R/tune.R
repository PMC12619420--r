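## Hyperparameter search: Gaussian-process-guided proposals (expected
## improvement over an RBF-kernel surrogate) with a pure-random fallback,
## returning the trialed configuration with the best validation loss.

.space_sample <- function(space, n) {
  sapply(space, function(rg) {
    if (isTRUE(attr(rg, "log")))
      exp(runif(n, log(rg[1]), log(rg[2])))
    else runif(n, rg[1], rg[2])
  })
}

.space_unit <- function(space, X) {
  U <- X
  for (j in seq_along(space)) {
    rg <- space[[j]]
    U[, j] <- if (isTRUE(attr(rg, "log")))
      (log(X[, j]) - log(rg[1])) / (log(rg[2]) - log(rg[1]))
    else (X[, j] - rg[1]) / (rg[2] - rg[1])
  }
  U
}

.gp_ei <- function(U, y, Ucand, lengthscale = 0.2, nugget = 1e-6) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  ys <- (y - mean(y)) / max(sd(y), 1e-12)
  K <- k(U, U) + diag(nugget + 1e-4, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  Ks <- k(Ucand, U)
  mu <- Ks %*% alpha
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- min(ys)
  imp <- best - mu
  zz <- imp / s
  ei <- imp * pnorm(zz) + s * dnorm(zz)
  as.vector(ei)
}

#' Hyperparameter search over a box
#'
#' Minimises \code{objective(params, train, validation)} over a named list
#' of numeric ranges. The first third of the budget is seeded random
#' exploration; the rest proposes the candidate with the highest expected
#' improvement under a Gaussian-process surrogate (set
#' \code{method = "random"} for pure random search). The returned best
#' entry always equals the minimum of the trial ledger.
#'
#' @param train,validation opaque data objects handed to the objective.
#' @param search_space named list; each element is \code{c(lo, hi)},
#'   optionally with \code{attr(., "log") = TRUE} for log-scale sampling.
#' @param budget number of trials (>= 1).
#' @param seed integer seed.
#' @param objective function(params, train, validation) -> scalar loss
#'   (lower is better); \code{params} is a named numeric vector. When
#'   omitted, \code{train}/\code{validation} must be lists with
#'   \code{features}, \code{treatment} and \code{outcome}, and the
#'   objective trains the representation stage under the proposed
#'   parameters and returns its validation factual loss.
#' @param method "gp" (default) or "random".
#' @param base_config configuration whose entries the searched parameters
#'   override (default objective only).
#' @return list with \code{best} (params + score), \code{trials}
#'   (data.frame ledger) and \code{config} (the best parameters merged
#'   into \code{base_config}).
#' @export
tune_hyperparameters <- function(train, validation, search_space, budget,
                                 seed = 1L, objective = NULL,
                                 method = c("gp", "random"),
                                 base_config = cfrflow_config()) {
  if (is.null(objective)) {
    objective <- function(params, train, validation) {
      cfgl <- unclass(base_config)
      for (nm in names(params)) {
        v <- params[[nm]]
        if (nm %in% c("rep_dim", "batch_size", "max_epochs", "patience",
                      "encoder_layers", "head_layers",
                      "flow_depth_stage1", "flow_depth_stage2"))
          v <- max(1L, as.integer(round(v)))
        cfgl[[nm]] <- v
      }
      cfg <- do.call(cfrflow_config,
                     cfgl[intersect(names(cfgl),
                                    names(formals(cfrflow_config)))])
      s0 <- train_stage0(train$features, train$treatment, train$outcome,
                         cfg, val = validation)
      s0$best_val_loss
    }
  }
  method <- match.arg(method)
  if (length(search_space) == 0) stopf("search space is empty")
  if (budget < 1) stopf("budget must be >= 1")
  dims <- names(search_space)
  if (is.null(dims)) stopf("search_space must be a named list")
  with_seed(seed, {
    n_init <- if (method == "random") budget else max(3L, ceiling(budget / 3))
    n_init <- min(n_init, budget)
    X <- matrix(NA_real_, budget, length(dims), dimnames = list(NULL, dims))
    y <- numeric(budget)
    X[seq_len(n_init), ] <- .space_sample(search_space, n_init)
    for (i in seq_len(budget)) {
      if (i > n_init) {
        cand <- .space_sample(search_space, 256)
        colnames(cand) <- dims
        ei <- tryCatch(
          .gp_ei(.space_unit(search_space, X[seq_len(i - 1), , drop = FALSE]),
                 y[seq_len(i - 1)],
                 .space_unit(search_space, cand)),
          error = function(e) runif(nrow(cand)))
        X[i, ] <- cand[which.max(ei), ]
      }
      y[i] <- objective(setNames(X[i, ], dims), train, validation)
    }
    trials <- data.frame(trial = seq_len(budget), X, score = y)
    best_i <- which.min(y)
    cfgl <- unclass(base_config)
    for (nm in dims) {
      v <- unname(X[best_i, nm])
      if (nm %in% c("rep_dim", "batch_size", "max_epochs", "patience",
                    "encoder_layers", "head_layers",
                    "flow_depth_stage1", "flow_depth_stage2"))
        v <- max(1L, as.integer(round(v)))
      cfgl[[nm]] <- v
    }
    best_cfg <- do.call(cfrflow_config,
                        cfgl[intersect(names(cfgl),
                                       names(formals(cfrflow_config)))])
    list(best = c(setNames(as.list(X[best_i, ]), dims),
                  list(score = y[best_i], trial = best_i)),
         trials = trials, config = best_cfg)
  })
}
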