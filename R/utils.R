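#' @importFrom stats plogis qlogis rnorm runif rbinom qnorm pnorm dnorm
#'   binomial coef glm lm predict quantile sd var vcov complete.cases
#'   setNames
#' @importFrom utils head read.csv write.csv
NULL

## let data.table's [ dispatch work inside this package
.datatable.aware <- TRUE

sigmoid <- function(x) plogis(x)
logit <- function(p) qlogis(p)

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed clinical tables round
#' half up (away from zero). `0.005 -> 0.01`, `-0.005 -> -0.01`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by a relative epsilon so values that are exactly *.xx5 in decimal
  # but stored minutely below it in binary still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream-specific child seed from a base seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

## Truncated-normal draws by inverse CDF (vectorised; lo/hi may be -Inf/Inf).
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}
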