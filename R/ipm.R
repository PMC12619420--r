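## Integral probability metric between treatment-arm representation clouds.
## Training uses an entropic-regularised (Sinkhorn) transport value on
## minibatches; a small-instance exact mode solves the 1-Wasserstein
## transport linear program and exists for verification.

euclid_cost <- function(A, B) {
  # pairwise Euclidean distances, rows of A vs rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  sqrt(pmax(D2, 0))
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

## Log-domain Sinkhorn with uniform marginals; returns the transport value
## <plan, cost> and the plan itself (used for gradients).
sinkhorn_plan <- function(A, B, epsilon = 0.1, n_iter = 100) {
  C <- euclid_cost(A, B)
  m <- nrow(A); n <- nrow(B)
  la <- -log(m); lb <- -log(n)
  M <- -C / epsilon
  f <- numeric(m); g <- numeric(n)
  for (it in seq_len(n_iter)) {
    f <- la - logsumexp_rows(sweep(M, 2, g, `+`))
    g <- lb - logsumexp_rows(t(M + f))
  }
  lp <- sweep(M + f, 2, g, `+`)
  plan <- exp(lp)
  list(value = sum(plan * C), plan = plan, cost = C)
}

## Exact 1-Wasserstein between small uniform point sets via the transport
## LP (boot::simplex); one redundant marginal constraint is dropped.
wasserstein_exact <- function(A, B) {
  m <- nrow(A); n <- nrow(B)
  if (m * n > 400)
    stopf("exact mode is for small instances (got %d x %d points)", m, n)
  C <- euclid_cost(A, B)
  ## a singleton side forces the plan to the product of the marginals
  if (m == 1L || n == 1L) return(sum(C) / (m * n))
  d <- as.vector(C)                       # pi_ij at index (j-1)*m + i
  nv <- m * n
  A3 <- matrix(0, m + n - 1L, nv)
  b3 <- numeric(m + n - 1L)
  for (i in seq_len(m)) {                 # row sums = 1/m
    A3[i, i + m * (seq_len(n) - 1L)] <- 1
    b3[i] <- 1 / m
  }
  for (j in seq_len(n - 1L)) {            # col sums = 1/n (last is redundant)
    A3[m + j, (j - 1L) * m + seq_len(m)] <- 1
    b3[m + j] <- 1 / n
  }
  sol <- boot::simplex(a = d, A3 = A3, b3 = b3, maxi = FALSE)
  if (sol$solved < 0) stopf("transport LP did not solve")
  sum(sol$soln * d)
}

#' Wasserstein integral probability metric between two point sets
#'
#' Discrepancy between the treated- and control-arm representation clouds,
#' as used by the balancing penalty of the representation stage. The
#' default estimator is the entropic-regularised (Sinkhorn) transport value
#' with uniform weights and Euclidean ground cost; \code{method = "exact"}
#' solves the 1-Wasserstein transport linear program and is intended for
#' small instances and verification.
#'
#' @param A,B numeric matrices (points in rows, same column dimension).
#' @param method \code{"sinkhorn"} or \code{"exact"}.
#' @param epsilon entropic regularisation strength (Sinkhorn only).
#' @param n_iter Sinkhorn iterations.
#' @return non-negative scalar.
#' @examples
#' a <- matrix(0); b <- matrix(3)
#' wasserstein_ipm(a, b, method = "exact")  # point masses 3 apart -> 3
#' @export
wasserstein_ipm <- function(A, B, method = c("sinkhorn", "exact"),
                            epsilon = 0.1, n_iter = 100) {
  method <- match.arg(method)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stopf("point sets must be nonempty")
  if (ncol(A) != ncol(B))
    stopf("dimension mismatch: %d vs %d columns", ncol(A), ncol(B))
  if (method == "exact") wasserstein_exact(A, B)
  else sinkhorn_plan(A, B, epsilon, n_iter)$value
}
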