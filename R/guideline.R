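## Deterministic guideline rule engine for first-line respiratory support.
## Encodes the ERS/ATS 2017 NIV indications and the ERS 2022 HFNC
## indications/first-line blockers over a structured clinical snapshot with
## explicit three-valued logic: every field can be unknown (NA), and a
## clause whose required fields are unknown is skipped (recorded, never
## silently failed).

.flag_names <- c("copd_exacerbation", "cardiogenic_pulmonary_edema",
                 "neuromuscular_disease", "obesity_hypoventilation",
                 "post_extubation", "post_extubation_high_risk",
                 "established_post_extubation_rf", "post_operative",
                 "immunocompromised", "de_novo_hypoxemic_rf",
                 "niv_intolerant", "niv_contraindicated", "chest_trauma")

.arf_levels <- c("none", "mild", "moderate", "severe", "unknown")

#' Structured clinical snapshot at the decision timestamp
#'
#' Most recent pre-decision values of the guideline-relevant physiology
#' plus condition flags. Every field may be \code{NA} (unknown);
#' \code{arf_severity} defaults to a severity derived from the
#' SpO2/FiO2 ratio when not supplied.
#'
#' @param ph arterial pH.
#' @param paco2 arterial CO2 tension (mmHg).
#' @param resp_rate respiratory rate (/min).
#' @param spo2 oxygen saturation (\%).
#' @param fio2 inspired oxygen fraction (0.21-1).
#' @param arf_severity one of none/mild/moderate/severe/unknown; derived
#'   from SpO2/FiO2 when NULL.
#' @param ... condition flags (logical or NA): copd_exacerbation,
#'   cardiogenic_pulmonary_edema, neuromuscular_disease,
#'   obesity_hypoventilation, post_extubation, post_extubation_high_risk,
#'   established_post_extubation_rf, post_operative, immunocompromised,
#'   de_novo_hypoxemic_rf, niv_intolerant, niv_contraindicated,
#'   chest_trauma. Unspecified flags default to FALSE.
#' @return an object of class \code{clinical_snapshot}.
#' @examples
#' clinical_snapshot(ph = 7.28, paco2 = 60, copd_exacerbation = TRUE)
#' @export
clinical_snapshot <- function(ph = NA, paco2 = NA, resp_rate = NA,
                              spo2 = NA, fio2 = NA, arf_severity = NULL,
                              ...) {
  flags <- list(...)
  bad <- setdiff(names(flags), .flag_names)
  if (length(bad)) stopf("unknown flag(s): %s", paste(bad, collapse = ", "))
  full <- setNames(as.list(rep(FALSE, length(.flag_names))), .flag_names)
  for (nm in names(flags)) full[[nm]] <- as.logical(flags[[nm]])
  num_chk <- function(x, what) {
    if (!is.na(x) && (!is.numeric(x) || x <= 0))
      stopf("%s must be positive when present", what)
    as.numeric(x)
  }
  ph <- num_chk(ph, "ph"); paco2 <- num_chk(paco2, "paco2")
  resp_rate <- num_chk(resp_rate, "resp_rate")
  spo2 <- num_chk(spo2, "spo2"); fio2 <- num_chk(fio2, "fio2")
  if (is.null(arf_severity))
    arf_severity <- derive_arf_severity(spo2, fio2, resp_rate)
  arf_severity <- match.arg(arf_severity, .arf_levels)
  structure(c(list(ph = ph, paco2 = paco2, resp_rate = resp_rate,
                   spo2 = spo2, fio2 = fio2, arf_severity = arf_severity),
              full),
            class = "clinical_snapshot")
}

#' Operational severity of acute respiratory failure
#'
#' Surrogate grading from the SpO2/FiO2 (S/F) ratio: severe when
#' S/F <= 148, moderate when <= 235; otherwise mild when substantial
#' oxygen support or tachypnoea is present (FiO2 >= 0.4 or RR > 24), else
#' none. Unknown when SpO2 or FiO2 is missing. Thresholds are exposed so
#' sites can substitute their own convention.
#'
#' @param spo2 oxygen saturation (\%).
#' @param fio2 inspired oxygen fraction.
#' @param resp_rate respiratory rate (/min; may be NA).
#' @param severe_sf,moderate_sf S/F cut-points.
#' @return character vector over none/mild/moderate/severe/unknown.
#' @export
derive_arf_severity <- function(spo2, fio2, resp_rate = NA,
                                severe_sf = 148, moderate_sf = 235) {
  sf <- spo2 / fio2
  out <- rep("unknown", length(sf))
  known <- !is.na(sf)
  mild <- (!is.na(fio2) & fio2 >= 0.4) | (!is.na(resp_rate) & resp_rate > 24)
  mild[is.na(mild)] <- FALSE
  out[known] <- ifelse(sf[known] <= severe_sf, "severe",
                       ifelse(sf[known] <= moderate_sf, "moderate",
                              ifelse(mild[known], "mild", "none")))
  out
}

#' Respiratory acidosis criterion
#'
#' TRUE iff pH <= 7.35 and PaCO2 > 45 mmHg (boundary values included per
#' the inequality directions); NA when the available fields leave the
#' conjunction undetermined.
#'
#' @param snapshot a \code{\link{clinical_snapshot}}, or an arterial pH
#'   value when \code{paco2} is given.
#' @param paco2 PaCO2 (mmHg), when calling with raw values.
#' @return TRUE/FALSE/NA.
#' @export
detect_respiratory_acidosis <- function(snapshot, paco2 = NULL) {
  if (inherits(snapshot, "clinical_snapshot")) {
    ph <- snapshot$ph; pc <- snapshot$paco2
  } else {
    ph <- snapshot; pc <- paco2
  }
  (ph <= 7.35) & (pc > 45)
}

## A clause outcome is TRUE (fired), FALSE, or NA (skipped: a required
## field is unknown).
.sev_in <- function(sev, set) {
  if (sev == "unknown") NA else sev %in% set
}

.mk_rec <- function(recommendation, confidence, clause_ids, skipped,
                    explanation) {
  structure(list(recommendation = recommendation, confidence = confidence,
                 explanation = explanation, clause_ids = clause_ids,
                 skipped_clauses = skipped),
            class = "modality_recommendation")
}

.verdict <- function(clauses, negations, label) {
  fired <- names(clauses)[vapply(clauses, isTRUE, TRUE)]
  skipped <- names(clauses)[vapply(clauses, is.na, TRUE)]
  neg_fired <- names(negations)[vapply(negations, isTRUE, TRUE)]
  skipped <- c(skipped, names(negations)[vapply(negations, is.na, TRUE)])
  conditional <- attr(clauses, "conditional") %||% character()
  uncond_fired <- setdiff(fired, conditional)
  if (length(fired)) {
    conf <- if (length(uncond_fired) || length(fired) >= 2) "high" else "low"
    expl <- sprintf("%s indicated: clause(s) %s fired%s.", label,
                    paste(fired, collapse = ", "),
                    if (length(skipped))
                      sprintf(" (skipped for missing data: %s)",
                              paste(skipped, collapse = ", ")) else "")
    rec <- .mk_rec("Yes", conf, fired, skipped, expl)
  } else if (length(neg_fired)) {
    rec <- .mk_rec("No", "high", neg_fired, skipped,
                   sprintf("%s not recommended: %s.", label,
                           paste(neg_fired, collapse = ", ")))
  } else {
    expl <- if (length(skipped))
      sprintf("No %s clause fired; clause(s) %s skipped for missing data.",
              label, paste(skipped, collapse = ", "))
    else sprintf("No %s indication or contraindication applies.", label)
    rec <- .mk_rec("Either", "medium", character(), skipped, expl)
  }
  attr(rec, "unconditional_fired") <- length(uncond_fired) > 0
  rec
}

#' Guideline assessment for noninvasive ventilation
#'
#' Applies the NIV indication clauses: COPD exacerbation with respiratory
#' acidosis (NIV-1); cardiogenic pulmonary edema (NIV-2); neuromuscular
#' disease or obesity hypoventilation with respiratory acidosis (NIV-3);
#' prophylactic use after extubation in high-risk patients (NIV-4);
#' immunocompromised patients with mild-to-moderate respiratory failure
#' (NIV-5, conditional, reported at low confidence). Negations: established
#' post-extubation respiratory failure (NIV-NEG-1) and low-risk
#' post-extubation prophylaxis (NIV-NEG-2).
#'
#' @param snapshot a \code{\link{clinical_snapshot}}.
#' @return a \code{modality_recommendation} (Yes/No/Either).
#' @export
assess_niv <- function(snapshot) {
  s <- snapshot
  acid <- detect_respiratory_acidosis(s)
  clauses <- list(
    "NIV-1" = s$copd_exacerbation & acid,
    "NIV-2" = s$cardiogenic_pulmonary_edema,
    "NIV-3" = (s$neuromuscular_disease | s$obesity_hypoventilation) & acid,
    "NIV-4" = s$post_extubation & s$post_extubation_high_risk &
      !s$established_post_extubation_rf,
    "NIV-5" = s$immunocompromised & .sev_in(s$arf_severity,
                                            c("mild", "moderate")))
  attr(clauses, "conditional") <- "NIV-5"
  negations <- list(
    "NIV-NEG-1" = s$established_post_extubation_rf,
    "NIV-NEG-2" = s$post_extubation & !s$post_extubation_high_risk)
  .verdict(clauses, negations, "NIV")
}

#' Guideline assessment for high-flow nasal cannula
#'
#' First-line blockers dominate: acute hypercapnic respiratory failure
#' unless NIV is contraindicated or not tolerated (HFNC-BLOCK-1), and a
#' clear (non-conditional) NIV indication in a patient who tolerates NIV
#' (HFNC-BLOCK-2). Indications: de novo hypoxemic respiratory failure
#' (HFNC-1); post-operative post-extubation high-risk patients (HFNC-2);
#' NIV intolerance with moderate-to-severe respiratory failure (HFNC-3);
#' moderate-to-severe respiratory failure without an NIV indication
#' (HFNC-4); post-operative respiratory failure (HFNC-5, conditional) and
#' chest trauma with respiratory failure (HFNC-6, conditional), both at
#' low confidence.
#'
#' @param snapshot a \code{\link{clinical_snapshot}}.
#' @param niv_assessment the result of \code{\link{assess_niv}} on the same
#'   snapshot (NIV precedence requires it).
#' @return a \code{modality_recommendation}.
#' @export
assess_hfnc <- function(snapshot, niv_assessment) {
  s <- snapshot
  acid <- detect_respiratory_acidosis(s)
  niv_ok_alt <- isTRUE(s$niv_contraindicated) | isTRUE(s$niv_intolerant)
  blockers <- list(
    "HFNC-BLOCK-1" = acid & !niv_ok_alt,
    "HFNC-BLOCK-2" = (niv_assessment$recommendation == "Yes" &&
                        isTRUE(attr(niv_assessment, "unconditional_fired"))) &
      !niv_ok_alt)
  blk_fired <- names(blockers)[vapply(blockers, isTRUE, TRUE)]
  blk_skipped <- names(blockers)[vapply(blockers, is.na, TRUE)]
  if (length(blk_fired)) {
    return(.mk_rec("No", "high", blk_fired, blk_skipped,
                   sprintf("HFNC not first line: %s.",
                           paste(blk_fired, collapse = ", "))))
  }
  arf_present <- .sev_in(s$arf_severity, c("mild", "moderate", "severe"))
  modsev <- .sev_in(s$arf_severity, c("moderate", "severe"))
  clauses <- list(
    "HFNC-1" = s$de_novo_hypoxemic_rf,
    "HFNC-2" = s$post_operative & s$post_extubation_high_risk,
    "HFNC-3" = s$niv_intolerant & modsev,
    "HFNC-4" = modsev & (niv_assessment$recommendation != "Yes"),
    "HFNC-5" = s$post_operative & arf_present,
    "HFNC-6" = s$chest_trauma & arf_present)
  attr(clauses, "conditional") <- c("HFNC-5", "HFNC-6")
  rec <- .verdict(clauses, list(), "HFNC")
  rec$skipped_clauses <- unique(c(rec$skipped_clauses, blk_skipped))
  rec
}

#' Alignment of a model recommendation with the guideline assessment
#'
#' Aligned when the model's modality is admissible (its assessment is Yes
#' or Either) and the opposite modality is not exclusively indicated; an
#' Indifferent model output is aligned whenever at least one modality is
#' admissible.
#'
#' @param model_modality "NIV", "HFNC" or "Indifferent".
#' @param assessment a \code{guideline_assessment} (or a list with
#'   \code{niv} and \code{hfnc} recommendations).
#' @return list(alignment = logical, explanation = character).
#' @export
check_alignment <- function(model_modality, assessment) {
  niv <- assessment$niv$recommendation
  hfnc <- assessment$hfnc$recommendation
  ok <- function(r) r %in% c("Yes", "Either")
  if (model_modality == "Indifferent") {
    al <- ok(niv) || ok(hfnc)
    expl <- if (al) "Indifferent is admissible: at least one modality is not contraindicated."
    else "Neither modality is guideline-admissible."
  } else {
    own <- if (model_modality == "NIV") niv else hfnc
    opp <- if (model_modality == "NIV") hfnc else niv
    al <- ok(own) && !(opp == "Yes" && own != "Yes")
    expl <- sprintf("Model chose %s; guideline verdicts NIV=%s, HFNC=%s.",
                    model_modality, niv, hfnc)
  }
  list(alignment = al, explanation = expl)
}

#' Full guideline assessment of a snapshot against a model recommendation
#'
#' @param snapshot a \code{\link{clinical_snapshot}}.
#' @param model_modality the model's provisional modality.
#' @return an object of class \code{guideline_assessment} with \code{niv},
#'   \code{hfnc} and \code{model_alignment} components.
#' @export
assess_guidelines <- function(snapshot, model_modality) {
  niv <- assess_niv(snapshot)
  hfnc <- assess_hfnc(snapshot, niv)
  a <- list(niv = niv, hfnc = hfnc)
  structure(c(a, list(model_alignment = check_alignment(model_modality, a))),
            class = "guideline_assessment")
}

#' @export
print.guideline_assessment <- function(x, ...) {
  cat(sprintf("NIV: %s (%s; %s)\n", x$niv$recommendation, x$niv$confidence,
              paste(x$niv$clause_ids, collapse = ",")))
  cat(sprintf("HFNC: %s (%s; %s)\n", x$hfnc$recommendation,
              x$hfnc$confidence, paste(x$hfnc$clause_ids, collapse = ",")))
  cat(sprintf("Model aligned: %s\n", x$model_alignment$alignment))
  invisible(x)
}

## admissibility of a modality under its recommendation: TRUE / FALSE / NA
## (NA = an Either verdict that rests on skipped clauses: undetermined)
.admissible <- function(rec) {
  if (rec$recommendation == "Yes") TRUE
  else if (rec$recommendation == "No") FALSE
  else if (length(rec$skipped_clauses)) NA
  else TRUE
}

#' Project a model recommendation onto the guideline-feasible set
#'
#' The block/correct/defer audit: an admissible model modality passes
#' unchanged; an inadmissible one is corrected to the admissible
#' alternative; when no modality is definitively admissible, or the
#' decisive fields are unknown, the recommendation is deferred
#' (modality Indifferent). An Indifferent model output with both
#' modalities admissible resolves to the arm with the lower estimated
#' risk, status unchanged.
#'
#' @param ite_estimate a row/list with \code{p_imv_niv}, \code{p_imv_hfnc}
#'   and \code{modality} (as produced by \code{\link{predict.cfrflow}}).
#' @param assessment a \code{guideline_assessment} for the same encounter.
#' @param snapshot optional snapshot (kept for rationale text).
#' @return an object of class \code{final_recommendation}: modality,
#'   status (unchanged/corrected/deferred), triggering_clauses, rationale.
#' @export
audit_and_project <- function(ite_estimate, assessment, snapshot = NULL) {
  model <- ite_estimate$modality
  adm <- c(NIV = .admissible(assessment$niv),
           HFNC = .admissible(assessment$hfnc))
  clauses_of <- function(m) {
    cl <- if (m == "NIV") assessment$niv$clause_ids
          else assessment$hfnc$clause_ids
    if (length(cl)) cl else "GL-DEFAULT"
  }
  fin <- function(modality, status, clauses, rationale)
    structure(list(modality = modality, status = status,
                   triggering_clauses = clauses, rationale = rationale),
              class = "final_recommendation")

  if (model %in% c("NIV", "HFNC")) {
    alt <- if (model == "NIV") "HFNC" else "NIV"
    if (isTRUE(adm[[model]]))
      return(fin(model, "unchanged", clauses_of(model),
                 sprintf("Model choice %s is guideline-admissible.", model)))
    if (is.na(adm[[model]]))
      return(fin("Indifferent", "deferred", "GL-DEFER-MISSING",
                 sprintf("Admissibility of %s undetermined (missing data); deferred to clinician review.",
                         model)))
    if (isTRUE(adm[[alt]]))
      return(fin(alt, "corrected", clauses_of(alt),
                 sprintf("Model choice %s blocked by guideline; corrected to %s.",
                         model, alt)))
    if (is.na(adm[[alt]]))
      return(fin("Indifferent", "deferred", "GL-DEFER-MISSING",
                 sprintf("%s blocked and %s undetermined; deferred.", model, alt)))
    return(fin("Indifferent", "deferred", "GL-DEFER-BLOCKED",
               "Both modalities blocked by guideline; deferred to clinician review."))
  }
  ## model Indifferent
  if (isTRUE(adm[["NIV"]]) && isTRUE(adm[["HFNC"]])) {
    pick <- if (ite_estimate$p_imv_niv < ite_estimate$p_imv_hfnc) "NIV"
            else if (ite_estimate$p_imv_hfnc < ite_estimate$p_imv_niv) "HFNC"
            else "NIV"   # exact tie: NIV carries the stronger indication set
    return(fin(pick, "unchanged", clauses_of(pick),
               sprintf("Model indifferent; both admissible; %s has the lower estimated IMV risk (%.4f vs %.4f).",
                       pick, min(ite_estimate$p_imv_niv, ite_estimate$p_imv_hfnc),
                       max(ite_estimate$p_imv_niv, ite_estimate$p_imv_hfnc))))
  }
  if (any(is.na(adm)))
    return(fin("Indifferent", "deferred", "GL-DEFER-MISSING",
               "Model indifferent and admissibility undetermined; deferred."))
  if (xor(isTRUE(adm[["NIV"]]), isTRUE(adm[["HFNC"]]))) {
    pick <- if (isTRUE(adm[["NIV"]])) "NIV" else "HFNC"
    return(fin(pick, "corrected", clauses_of(pick),
               sprintf("Model indifferent; only %s is guideline-admissible.",
                       pick)))
  }
  fin("Indifferent", "deferred", "GL-DEFER-BLOCKED",
      "Model indifferent and both modalities blocked; deferred.")
}
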