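## Feature pipeline: hourly binning, forward-fill/mean imputation, baseline,
## local trend, and time-since-last-measurement (TSLM) features, all
## relative to the decision timestamp T0.

#' Resample observations of one encounter into hourly bins
#'
#' Bins are consecutive one-hour intervals ending at T0, labelled
#' \code{-(horizon-1), ..., 0}: an observation taken \code{h} hours before
#' T0 falls in bin \code{-floor(h)} (bin 0 is the last hour). Each bin holds
#' the mean of the observations falling in it; empty bins are missing.
#'
#' @param observations data.frame with columns \code{variable},
#'   \code{hours_before_t0} (non-negative = before T0) and \code{value}.
#' @param horizon_hours window length (number of bins), at least 1.
#' @param variables optional character vector fixing the variable set and
#'   order; defaults to the sorted variables present.
#' @return a \code{ts_grid}: list with \code{variables}, \code{bins},
#'   \code{grid} (variables x bins matrix, NA = missing) and
#'   \code{measured_mask}.
#' @export
resample_hourly <- function(observations, horizon_hours = 48,
                            variables = NULL) {
  if (horizon_hours < 1) stopf("horizon_hours must be >= 1")
  hb <- observations$hours_before_t0
  after <- which(hb < 0)
  if (length(after)) {
    warning(sprintf("%d observation(s) after T0 excluded", length(after)))
    observations <- observations[-after, , drop = FALSE]
    hb <- observations$hours_before_t0
  }
  inside <- hb < horizon_hours
  observations <- observations[inside, , drop = FALSE]
  hb <- hb[inside]
  if (is.null(variables))
    variables <- sort(unique(as.character(observations$variable)))
  bins <- seq.int(-(horizon_hours - 1), 0)
  grid <- matrix(NA_real_, length(variables), length(bins),
                 dimnames = list(variables, bins))
  if (nrow(observations)) {
    bin <- -floor(hb)
    key <- interaction(factor(as.character(observations$variable),
                              levels = variables),
                       factor(bin, levels = bins), drop = TRUE)
    m <- tapply(observations$value, key, mean)
    parts <- strsplit(names(m), ".", fixed = TRUE)
    vi <- match(vapply(parts, `[`, "", 1L), variables)
    bi <- match(vapply(parts, function(p) paste(p[-1], collapse = "."), ""),
                as.character(bins))
    grid[cbind(vi, bi)] <- as.numeric(m)
  }
  structure(list(variables = variables, bins = bins, grid = grid,
                 measured_mask = !is.na(grid)),
            class = "ts_grid")
}

#' Impute a resampled grid
#'
#' A missing bin takes the most recent observed value within the same
#' encounter when that value is at most 24 hours old (inclusive at exactly
#' 24 h); otherwise the variable's population mean. No missing cells remain;
#' the measured mask is unchanged.
#'
#' @param grid a \code{ts_grid}.
#' @param population_means named numeric vector with one entry per grid
#'   variable (computed on the training split only).
#' @param max_carry_hours carry-forward limit (default 24).
#' @return the imputed \code{ts_grid}.
#' @export
impute_grid <- function(grid, population_means, max_carry_hours = 24) {
  miss <- setdiff(grid$variables, names(population_means))
  if (length(miss))
    stopf("population_means missing variable(s): %s",
          paste(miss, collapse = ", "))
  g <- grid$grid
  for (v in grid$variables) {
    row <- g[v, ]
    obs_idx <- which(!is.na(row))
    if (length(obs_idx) == 0L) {
      g[v, ] <- population_means[[v]]
      next
    }
    last <- cumsum(!is.na(row))          # index into obs_idx, 0 before first
    fill <- which(is.na(row))
    src <- last[fill]
    val <- rep(population_means[[v]], length(fill))
    has_prev <- src > 0L
    if (any(has_prev)) {
      gap <- fill[has_prev] - obs_idx[src[has_prev]]
      carried <- gap <= max_carry_hours
      val[has_prev][carried] <- row[obs_idx[src[has_prev]]][carried]
    }
    g[v, fill] <- val
  }
  grid$grid <- g
  grid
}

#' Hours since last measurement at T0
#'
#' @param grid a \code{ts_grid} (imputed or not; uses the measured mask).
#' @return named numeric vector: \code{-b} where \code{b} is the most recent
#'   measured bin, or \code{horizon + 1} as the never-measured sentinel.
#' @export
tslm <- function(grid) {
  horizon <- length(grid$bins)
  setNames(vapply(seq_along(grid$variables), function(i) {
    idx <- which(grid$measured_mask[i, ])
    if (length(idx) == 0L) horizon + 1 else -grid$bins[max(idx)]
  }, numeric(1)), grid$variables)
}

#' Local trend over the trailing window
#'
#' Ordinary least-squares slope (units per hour) of each variable's imputed
#' series over the last \code{window_hours} bins.
#'
#' @param grid an imputed \code{ts_grid}.
#' @param window_hours trailing window length in bins (>= 2).
#' @return named numeric vector of slopes.
#' @export
local_trend <- function(grid, window_hours = 6) {
  if (window_hours < 2) stopf("window_hours must cover at least 2 bins")
  H <- length(grid$bins)
  w <- min(window_hours, H)
  x <- grid$bins[(H - w + 1):H]
  Y <- grid$grid[, (H - w + 1):H, drop = FALSE]
  if (anyNA(Y)) stopf("local_trend requires an imputed grid")
  xc <- x - mean(x)
  setNames(drop(Y %*% xc) / sum(xc^2), grid$variables)
}

#' Baseline value per variable
#'
#' The earliest observed value in the encounter window; the population mean
#' when the variable was never measured.
#'
#' @param grid a \code{ts_grid}.
#' @param population_means named numeric fallback means.
#' @return named numeric vector.
#' @export
baseline_values <- function(grid, population_means) {
  setNames(vapply(seq_along(grid$variables), function(i) {
    idx <- which(grid$measured_mask[i, ])
    if (length(idx) == 0L) population_means[[grid$variables[i]]]
    else grid$grid[i, min(idx)]
  }, numeric(1)), grid$variables)
}

#' Per-variable population means of observed values
#'
#' @param observations long-format observation table.
#' @param encounter_ids optional ids restricting the computation (use the
#'   training split to avoid leakage).
#' @return named numeric vector of means.
#' @export
population_means <- function(observations, encounter_ids = NULL) {
  if (!is.null(encounter_ids))
    observations <- observations[observations$encounter_id %in% encounter_ids, ]
  c(tapply(observations$value, as.character(observations$variable), mean))
}

.static_features <- c("age", "gender_male", "cci", "sofa", "ventio_score",
                      "chf", "copd", "copd_exacerbation",
                      "cardiogenic_pulmonary_edema", "de_novo_hypoxemic_rf",
                      "post_extubation", "immunocompromised")

#' Assemble the per-encounter feature matrix
#'
#' For every time-varying variable: current (last-bin) value, baseline,
#' local trend and TSLM; plus static demographics, severity scores and
#' condition flags. Simulator ground-truth (\code{oracle_}) columns are
#' excluded by construction. Feature order is fixed and identical across
#' encounters; the matrix contains no missing values.
#'
#' @param cohort an \code{icu_cohort}.
#' @param horizon_hours binning window (default 48).
#' @param window_hours trend window (default 6).
#' @param means population means (named vector); computed from
#'   \code{train_ids} when NULL.
#' @param train_ids encounter ids of the training split used to compute
#'   population means (defaults to all encounters).
#' @return list with \code{features} (numeric matrix, rownames =
#'   encounter ids), \code{feature_names}, and \code{means} (for reuse on a
#'   held-out split).
#' @export
assemble_features <- function(cohort, horizon_hours = 48, window_hours = 6,
                              means = NULL, train_ids = NULL) {
  enc <- strip_oracle(cohort$encounters)
  obs <- cohort$observations
  if (is.null(means))
    means <- population_means(obs, train_ids %||% enc$encounter_id)
  vars <- sort(names(means))
  feat_names <- c(as.vector(t(outer(vars, c("current", "baseline", "trend",
                                            "tslm"), paste, sep = "_"))),
                  .static_features)
  stopifnot(!any(startsWith(feat_names, .oracle_prefix)))

  split_obs <- split(as.data.frame(obs)[c("variable", "hours_before_t0",
                                          "value")],
                     factor(obs$encounter_id, levels = enc$encounter_id))
  ts_block <- t(vapply(split_obs, function(o) {
    g <- resample_hourly(o, horizon_hours, variables = vars)
    gi <- impute_grid(g, means)
    cur <- gi$grid[, ncol(gi$grid)]
    as.vector(rbind(cur, baseline_values(g, means),
                    local_trend(gi, window_hours), tslm(g)))
  }, numeric(4 * length(vars))))

  statics <- cbind(age = enc$age,
                   gender_male = as.numeric(enc$gender == "M"),
                   cci = enc$cci, sofa = enc$sofa,
                   ventio_score = enc$ventio_score,
                   chf = as.numeric(enc$chf), copd = as.numeric(enc$copd),
                   copd_exacerbation = as.numeric(enc$copd_exacerbation),
                   cardiogenic_pulmonary_edema =
                     as.numeric(enc$cardiogenic_pulmonary_edema),
                   de_novo_hypoxemic_rf = as.numeric(enc$de_novo_hypoxemic_rf),
                   post_extubation = as.numeric(enc$post_extubation),
                   immunocompromised = as.numeric(enc$immunocompromised))
  mat <- cbind(ts_block, statics)
  dimnames(mat) <- list(enc$encounter_id, feat_names)
  if (anyNA(mat)) stopf("assembled features contain missing values")
  list(features = mat, feature_names = feat_names, means = means)
}
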