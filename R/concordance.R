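## Concordance-versus-outcome evaluation: agreement between the final
## recommendation and the treatment actually received, stratified outcome
## rates with relative reduction/increase, and covariate-adjusted odds
## ratios.

#' Concordance label for one encounter
#'
#' Concordant when the final recommended modality equals the received
#' treatment; Indifferent (or deferred) recommendations are excluded from
#' concordance strata.
#'
#' @param final a \code{final_recommendation}, or a modality string.
#' @param received "NIV" or "HFNC".
#' @return "concordant", "discordant" or "excluded".
#' @export
label_concordance <- function(final, received) {
  modality <- if (inherits(final, "final_recommendation")) final$modality
              else as.character(final)
  if (!received %in% c("NIV", "HFNC"))
    stopf("received treatment must be NIV or HFNC")
  if (modality == "Indifferent") "excluded"
  else if (modality == received) "concordant"
  else "discordant"
}

#' Outcome rate as a printed percentage
#'
#' \code{100 * events / size}, rounded half-up to 2 decimals. A size of
#' zero yields NA (undefined rate).
#'
#' @param events event count.
#' @param size group size.
#' @return percentage (2 dp) or NA.
#' @export
rate_pct <- function(events, size) {
  ifelse(size >= 1, round_half_up(100 * events / size, 2), NA_real_)
}

#' Relative reduction in the concordant group
#'
#' \code{100 * (total rate - concordant rate) / total rate}, computed from
#' exact count ratios and only then rounded half-up to 2 decimals (the
#' rounded printed rates would give a different last digit).
#'
#' @param e_total,n_total events and size of the whole stratum.
#' @param e_conc,n_conc events and size of the concordant group.
#' @return percentage (2 dp); NA when the total rate is zero.
#' @export
relative_reduction <- function(e_total, n_total, e_conc, n_conc) {
  rt <- e_total / n_total
  rc <- e_conc / n_conc
  ifelse(rt > 0, round_half_up(100 * (rt - rc) / rt, 2), NA_real_)
}

#' Relative increase in the discordant group
#'
#' \code{100 * (discordant rate - total rate) / total rate}, from exact
#' count ratios.
#'
#' @param e_total,n_total events and size of the whole stratum.
#' @param e_disc,n_disc events and size of the discordant group.
#' @return percentage (2 dp); NA when the total rate is zero.
#' @export
relative_increase <- function(e_total, n_total, e_disc, n_disc) {
  rt <- e_total / n_total
  rd <- e_disc / n_disc
  ifelse(rt > 0, round_half_up(100 * (rd - rt) / rt, 2), NA_real_)
}

#' Concordance strata counts for a cohort
#'
#' One stratum per (recommended modality in NIV/HFNC) x (outcome in
#' IMV, mortality/hospice). Count invariants
#' (concordant + discordant = total, per group events <= sizes) are
#' asserted on every call.
#'
#' @param encounters data.frame with \code{encounter_id},
#'   \code{treatment_received}, \code{imv}, \code{mortality_or_hospice}.
#' @param recommendations data.frame with \code{encounter_id} and
#'   \code{modality} (the final recommendation; Indifferent rows are
#'   excluded).
#' @param model_label label naming the recommendation source.
#' @return data.frame of class \code{concordance_strata} with counts,
#'   rates and relative-change columns.
#' @export
tabulate_concordance <- function(encounters, recommendations,
                                 model_label = "model") {
  m <- match(recommendations$encounter_id, encounters$encounter_id)
  if (anyNA(m))
    stopf("unmatched encounter id(s): %s",
          paste(utils::head(recommendations$encounter_id[is.na(m)], 3),
                collapse = ", "))
  enc <- encounters[m, ]
  rec <- recommendations$modality
  outcomes <- list(IMV = as.numeric(enc$imv),
                   mortality_hospice = as.numeric(enc$mortality_or_hospice))
  rows <- list()
  for (modality in c("NIV", "HFNC")) {
    sel <- rec == modality
    conc <- sel & enc$treatment_received == modality
    disc <- sel & enc$treatment_received != modality
    for (oc in names(outcomes)) {
      y <- outcomes[[oc]]
      st <- data.frame(
        model_label = model_label, recommendation = modality,
        outcome_name = oc,
        n_total = sum(sel), e_total = sum(y[sel]),
        n_concordant = sum(conc), e_concordant = sum(y[conc]),
        n_discordant = sum(disc), e_discordant = sum(y[disc]),
        stringsAsFactors = FALSE)
      stopifnot(st$n_concordant + st$n_discordant == st$n_total,
                st$e_concordant + st$e_discordant == st$e_total,
                st$e_total <= st$n_total)
      rows[[length(rows) + 1L]] <- st
    }
  }
  out <- do.call(rbind, rows)
  out$rate_total <- rate_pct(out$e_total, out$n_total)
  out$rate_concordant <- rate_pct(out$e_concordant, out$n_concordant)
  out$rate_discordant <- rate_pct(out$e_discordant, out$n_discordant)
  out$relative_reduction_concordant <- ifelse(
    out$n_concordant >= 1,
    relative_reduction(out$e_total, out$n_total, out$e_concordant,
                       out$n_concordant), NA_real_)
  out$relative_increase_discordant <- ifelse(
    out$n_discordant >= 1,
    relative_increase(out$e_total, out$n_total, out$e_discordant,
                      out$n_discordant), NA_real_)
  class(out) <- c("concordance_strata", "data.frame")
  out
}

#' Covariate-adjusted association between concordant care and outcome
#'
#' Maximum-likelihood logistic regression of the outcome on the
#' concordance indicator and the standard confounder set (age, gender,
#' Charlson comorbidity index, SOFA score, early-warning risk score), with
#' Wald 95\% confidence intervals on the odds-ratio scale.
#'
#' @param rows data.frame with columns \code{outcome} (0/1),
#'   \code{concordant} (0/1), \code{age}, \code{gender} ("M"/"F" or 0/1),
#'   \code{cci}, \code{sofa}, \code{ventio_score}.
#' @return data.frame of class \code{adjusted_effects}: term, odds_ratio,
#'   ci_low, ci_high, p_value, unstable (separation flag).
#' @export
adjusted_association <- function(rows) {
  need <- c("outcome", "concordant", "age", "gender", "cci", "sofa",
            "ventio_score")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(rows) < 25) stopf("need at least 25 rows, got %d", nrow(rows))
  if (!all(complete.cases(rows[need]))) stopf("missing covariate values")
  if (is.character(rows$gender) || is.factor(rows$gender))
    rows$gender <- as.numeric(as.character(rows$gender) == "M")
  fit <- glm(outcome ~ concordant + age + gender + cci + sofa + ventio_score,
             family = binomial(), data = rows)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  unstable <- abs(cf) > 10 | se > 10 | !fit$converged
  if (any(unstable[-1]))
    warning("possible separation: coefficient(s) unstable, CI unreliable")
  out <- data.frame(term = names(cf),
                    odds_ratio = exp(cf),
                    ci_low = exp(cf - 1.96 * se),
                    ci_high = exp(cf + 1.96 * se),
                    p_value = 2 * pnorm(-abs(z)),
                    unstable = unstable,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("adjusted_effects", "data.frame")
  out
}

#' Write the evaluation report files
#'
#' \code{concordance.csv} mirrors the stratified-rate table layout (counts,
#' rates, relative reduction/increase); \code{adjusted.json} holds the
#' odds-ratio table. Re-reading reproduces the inputs.
#'
#' @param strata a \code{concordance_strata} table.
#' @param effects an \code{adjusted_effects} table (or NULL).
#' @param out_dir output directory.
#' @return \code{out_dir}, invisibly.
#' @export
build_report <- function(strata, effects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(strata),
                   file.path(out_dir, "concordance.csv"), row.names = FALSE)
  jsonlite::write_json(as.data.frame(effects %||% data.frame()),
                       file.path(out_dir, "adjusted.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(out_dir)
}

#' Read back a report directory
#'
#' @param out_dir directory written by \code{\link{build_report}}.
#' @return list with \code{strata} and \code{effects}.
#' @export
read_report <- function(out_dir) {
  strata <- utils::read.csv(file.path(out_dir, "concordance.csv"),
                            stringsAsFactors = FALSE)
  class(strata) <- c("concordance_strata", "data.frame")
  effects <- jsonlite::fromJSON(file.path(out_dir, "adjusted.json"))
  if (length(effects)) class(effects) <- c("adjusted_effects", "data.frame")
  list(strata = strata, effects = effects)
}
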