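## Conditional normalizing flow on a scalar latent.
##
## Each layer is a strictly monotone map in the normalizing (data -> base)
## direction, with parameters that are linear in the conditioning vector c:
##
##   u  = exp(s(c)) * z + t(c)
##   z' = u + alpha(c) * tanh(u),   alpha = 0.9 * tanh(g(c))
##
## |alpha| < 0.9 keeps the derivative positive, so the layer is invertible
## (the tanh part by Newton iteration). Zero-initialised parameters give the
## identity map over a standard-normal base. Depth-stacked layers model
## skewed/heavy-tailed conditional densities; the conditional mean and
## spread are carried by the affine parts.

.amax <- 0.9

#' Construct a conditional scalar flow
#'
#' @param context_dim dimension of the conditioning vector (0 for an
#'   unconditional flow).
#' @param depth number of layers (default 4).
#' @return an untrained \code{cond_flow} (identity map).
#' @export
cond_flow <- function(context_dim, depth = 4) {
  layers <- lapply(seq_len(depth), function(i)
    list(Ws = numeric(context_dim), bs = 0,
         Wt = numeric(context_dim), bt = 0,
         Wg = numeric(context_dim), bg = 0))
  structure(list(layers = layers, context_dim = context_dim, depth = depth),
            class = "cond_flow")
}

## context matrix helper: C may be NULL (unconditional) -> zero columns
.ctx <- function(C, n) {
  if (is.null(C)) matrix(0, n, 0) else as.matrix(C)
}

## Normalizing direction z -> eps with per-layer caches and log|d eps/d z|.
flow_normalize <- function(flow, z, C = NULL) {
  n <- length(z)
  C <- .ctx(C, n)
  if (ncol(C) != flow$context_dim)
    stopf("context has %d columns, flow expects %d", ncol(C), flow$context_dim)
  caches <- vector("list", flow$depth)
  ld <- numeric(n)
  for (l in seq_len(flow$depth)) {
    p <- flow$layers[[l]]
    s <- drop(C %*% p$Ws) + p$bs
    a <- exp(s)
    gam <- drop(C %*% p$Wg) + p$bg
    alpha <- .amax * tanh(gam)
    tt <- drop(C %*% p$Wt) + p$bt
    u <- a * z + tt
    h <- tanh(u)
    q <- 1 - h^2
    denom <- 1 + alpha * q
    z_new <- u + alpha * h
    ld <- ld + s + log(denom)
    caches[[l]] <- list(z = z, s = s, a = a, gam = gam, alpha = alpha,
                        u = u, h = h, q = q, denom = denom)
    z <- z_new
  }
  list(eps = z, logdet = ld, caches = caches, C = C)
}

## Generative direction eps -> z (inverse of flow_normalize).
flow_generate <- function(flow, eps, C = NULL) {
  n <- length(eps)
  C <- .ctx(C, n)
  z <- eps
  for (l in rev(seq_len(flow$depth))) {
    p <- flow$layers[[l]]
    s <- drop(C %*% p$Ws) + p$bs
    alpha <- .amax * tanh(drop(C %*% p$Wg) + p$bg)
    tt <- drop(C %*% p$Wt) + p$bt
    ## solve u + alpha*tanh(u) = z by Newton (monotone, deriv >= 1-.amax)
    u <- z
    for (it in 1:50) {
      r <- u + alpha * tanh(u) - z
      u <- u - r / (1 + alpha * (1 - tanh(u)^2))
      if (max(abs(r)) < 1e-13) break
    }
    z <- (u - tt) / exp(s)
  }
  z
}

#' Log-density of a conditional flow
#'
#' Change-of-variables density with a standard normal base.
#'
#' @param flow a \code{cond_flow}.
#' @param z scalar observations.
#' @param C conditioning matrix (one row per observation) or NULL.
#' @return log-density vector.
#' @export
flow_logpdf <- function(flow, z, C = NULL) {
  fw <- flow_normalize(flow, z, C)
  dnorm(fw$eps, log = TRUE) + fw$logdet
}

#' Sample from a conditional flow
#'
#' @param flow a \code{cond_flow}.
#' @param C conditioning matrix (its row count sets the sample size) or an
#'   integer sample size for an unconditional flow.
#' @param eps optional base-normal draws (for common random numbers);
#'   sampled internally otherwise.
#' @param seed seed used when \code{eps} is NULL.
#' @return scalar draws, one per row of \code{C}.
#' @export
flow_sample <- function(flow, C = NULL, eps = NULL, seed = 1L) {
  n <- if (is.matrix(C) || is.data.frame(C)) nrow(C) else as.integer(C %||% 1L)
  Cm <- if (is.matrix(C) || is.data.frame(C)) as.matrix(C) else NULL
  if (is.null(eps)) eps <- with_seed(seed, rnorm(n))
  flow_generate(flow, eps, Cm)
}

## Mean NLL and gradients for all layer parameters (manual reverse mode).
flow_nll_grad <- function(flow, z, C = NULL) {
  fw <- flow_normalize(flow, z, C)
  n <- length(z)
  Cm <- fw$C
  nll <- mean(0.5 * fw$eps^2 + 0.5 * log(2 * pi) - fw$logdet)
  w <- -1 / n                               # dL/d(logdet_i)
  gz <- fw$eps / n                          # dL/d(eps_i)
  grads <- vector("list", flow$depth)
  for (l in rev(seq_len(flow$depth))) {
    cc <- fw$caches[[l]]
    ## z' = u + alpha h;  u = a z + tt;  ld = s + log(denom)
    du <- gz * (1 + cc$alpha * cc$q) +
      w * (cc$alpha * (-2 * cc$h * cc$q)) / cc$denom
    dalpha <- gz * cc$h + w * cc$q / cc$denom
    dgam <- dalpha * .amax * (1 - tanh(cc$gam)^2)
    da <- du * cc$z
    ds <- da * cc$a + w
    dtt <- du
    gz <- du * cc$a                         # dL/d z_in
    grads[[l]] <- list(
      Ws = drop(crossprod(Cm, ds)), bs = sum(ds),
      Wt = drop(crossprod(Cm, dtt)), bt = sum(dtt),
      Wg = drop(crossprod(Cm, dgam)), bg = sum(dgam))
  }
  list(nll = nll, grads = grads)
}

#' Fit a conditional flow by maximum likelihood
#'
#' Full-batch Adam on the exact negative log-likelihood, with early
#' stopping on a held-out fraction.
#'
#' @param flow a \code{cond_flow}.
#' @param z scalar training observations.
#' @param C conditioning matrix or NULL.
#' @param lr Adam learning rate.
#' @param max_epochs iteration cap.
#' @param patience early-stopping patience (validation NLL).
#' @param val_frac held-out fraction for early stopping.
#' @param seed seed for the split.
#' @return the fitted flow, with a \code{training_log} attribute
#'   (data.frame of train/validation NLL per epoch).
#' @export
flow_fit <- function(flow, z, C = NULL, lr = 0.05, max_epochs = 400,
                     patience = 20, val_frac = 0.2, seed = 1L) {
  n <- length(z)
  if (sd(z) < 1e-12) stopf("degenerate (constant) target: cannot fit a density")
  Cm <- .ctx(C, n)
  idx_val <- with_seed(seed, sample(n, max(1L, floor(val_frac * n))))
  tr <- setdiff(seq_len(n), idx_val)
  ztr <- z[tr]; Ctr <- Cm[tr, , drop = FALSE]
  zva <- z[idx_val]; Cva <- Cm[idx_val, , drop = FALSE]

  params <- flow$layers
  m <- rapply(params, function(x) x * 0, how = "replace")
  v <- m; t_ad <- 0
  best <- list(nll = Inf, layers = params, epoch = 0L)
  log_df <- data.frame(epoch = integer(), train_nll = numeric(),
                       val_nll = numeric())
  wait <- 0L
  for (ep in seq_len(max_epochs)) {
    flow$layers <- params
    gr <- flow_nll_grad(flow, ztr, Ctr)
    t_ad <- t_ad + 1
    bc1 <- 1 - 0.9^t_ad; bc2 <- 1 - 0.999^t_ad
    for (l in seq_along(params)) for (nm in names(params[[l]])) {
      g <- gr$grads[[l]][[nm]]
      m[[l]][[nm]] <- 0.9 * m[[l]][[nm]] + 0.1 * g
      v[[l]][[nm]] <- 0.999 * v[[l]][[nm]] + 0.001 * g^2
      params[[l]][[nm]] <- params[[l]][[nm]] -
        lr * (m[[l]][[nm]] / bc1) / (sqrt(v[[l]][[nm]] / bc2) + 1e-8)
    }
    flow$layers <- params
    vn <- -mean(flow_logpdf(flow, zva, Cva))
    log_df <- rbind(log_df, data.frame(epoch = ep, train_nll = gr$nll,
                                       val_nll = vn))
    if (vn < best$nll - 1e-6) {
      best <- list(nll = vn, layers = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  flow$layers <- best$layers
  attr(flow, "training_log") <- log_df
  attr(flow, "best_epoch") <- best$epoch
  flow
}
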