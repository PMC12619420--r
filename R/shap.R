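## Shapley-value feature attribution by permutation sampling against a
## background sample (marginal expectations). Exact for additive models:
## the attribution of feature j is f's coefficient times
## (x_j - mean background_j) irrespective of the permutation.

#' Shapley attributions of a prediction function at one point
#'
#' @param f function taking a feature matrix and returning a numeric
#'   vector (one value per row).
#' @param x single feature vector (named, or matching background columns).
#' @param background background feature matrix (the reference
#'   distribution).
#' @param n_perm number of sampled feature permutations.
#' @param seed integer seed.
#' @return named numeric vector of per-feature attributions summing to
#'   \code{f(x) - mean(f(background))} (up to sampling error).
#' @export
shap_values <- function(f, x, background, n_perm = 16, seed = 1L) {
  B <- as.matrix(background)
  d <- ncol(B)
  x <- as.numeric(x)
  if (length(x) != d) stopf("x must have %d features", d)
  phi <- numeric(d)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample(d)
      Z <- B
      prev <- mean(f(Z))
      for (j in perm) {
        Z[, j] <- x[j]
        cur <- mean(f(Z))
        phi[j] <- phi[j] + (cur - prev)
        prev <- cur
      }
    }
  })
  setNames(phi / n_perm, colnames(B))
}

#' Top-k features driving the estimated treatment effect
#'
#' Ranks features by the mean absolute Shapley attribution of the model's
#' head-based effect output (NIV risk minus HFNC risk at the
#' representation) across the supplied encounters.
#'
#' @param model a fitted \code{\link{cfrflow}}, or a prediction function
#'   as in \code{\link{shap_values}}.
#' @param features feature matrix of the encounters to explain.
#' @param background background feature matrix.
#' @param k number of features to return (default 50).
#' @param n_perm permutations per encounter.
#' @param seed integer seed.
#' @return data.frame (feature, attribution) sorted by decreasing
#'   magnitude; all features (with a warning) when \code{k} exceeds the
#'   dimension.
#' @export
rank_features_shap <- function(model, features, background, k = 50,
                               n_perm = 8, seed = 1L) {
  f <- if (is.function(model)) model else function(X) {
    R <- encode_features(model$stage0, X)
    head_risk(model$stage0, R, 1) - head_risk(model$stage0, R, 0)
  }
  X <- as.matrix(features)
  if (is.null(dim(X)) || nrow(X) == 1) X <- matrix(X, nrow = 1,
                                                   dimnames = list(NULL, colnames(features)))
  d <- ncol(X)
  if (k > d) {
    warning(sprintf("k = %d exceeds the %d available features; returning all",
                    k, d))
    k <- d
  }
  mags <- matrix(0, nrow(X), d)
  for (i in seq_len(nrow(X)))
    mags[i, ] <- shap_values(f, X[i, ], background, n_perm,
                             seed = child_seed(seed, i))
  m <- colMeans(abs(mags))
  names(m) <- colnames(background)
  ord <- order(m, decreasing = TRUE)[seq_len(k)]
  data.frame(feature = names(m)[ord], attribution = unname(m[ord]),
             stringsAsFactors = FALSE)
}
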