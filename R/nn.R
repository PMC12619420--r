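## Minimal multilayer-perceptron machinery (ReLU hidden units, linear
## output) with reverse-mode gradients and Adam. Written against plain
## matrices; every function is pure apart from RNG consumption at init.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                           sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

## Forward pass; drop_masks (list per hidden layer, or NULL) implements
## inverted dropout and is supplied by the training loop for determinism.
mlp_forward <- function(net, X, drop_masks = NULL) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
    if (l < L) {
      Z <- Z * (Z > 0)
      if (!is.null(drop_masks)) Z <- Z * drop_masks[[l]]
    }
    A[[l + 1]] <- Z
  }
  list(out = A[[L + 1]], A = A, drop_masks = drop_masks)
}

## Backward pass given dL/d(output); returns parameter grads and dL/dX.
mlp_backward <- function(net, cache, dout) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
    if (l > 1L) {
      delta <- delta * (cache$A[[l]] > 0)
      if (!is.null(cache$drop_masks))
        delta <- delta * cache$drop_masks[[l - 1L]]
    }
  }
  list(gW = gW, gb = gb, dX = delta)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    g <- grads$gW[[l]] + weight_decay * net$W[[l]]
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * g
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * g^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    g <- grads$gb[[l]]
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * g
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * g^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
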