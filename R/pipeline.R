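#' Build a clinical snapshot from an encounter row
#'
#' @param row single-row data.frame from a cohort's encounter table.
#' @return a \code{\link{clinical_snapshot}}.
#' @export
snapshot_from_encounter <- function(row) {
  clinical_snapshot(
    ph = row$ph, paco2 = row$paco2, resp_rate = row$resp_rate,
    spo2 = row$spo2, fio2 = row$fio2,
    arf_severity = if ("arf_severity" %in% names(row)) row$arf_severity else NULL,
    copd_exacerbation = row$copd_exacerbation,
    cardiogenic_pulmonary_edema = row$cardiogenic_pulmonary_edema,
    neuromuscular_disease = row$neuromuscular_disease,
    obesity_hypoventilation = row$obesity_hypoventilation,
    post_extubation = row$post_extubation,
    post_extubation_high_risk = row$post_extubation_high_risk,
    established_post_extubation_rf = row$established_post_extubation_rf,
    post_operative = row$post_operative,
    immunocompromised = row$immunocompromised,
    de_novo_hypoxemic_rf = row$de_novo_hypoxemic_rf,
    niv_intolerant = row$niv_intolerant,
    niv_contraindicated = row$niv_contraindicated,
    chest_trauma = row$chest_trauma)
}

#' Guideline-audited recommendations for a cohort
#'
#' Runs the rule engine and the block/correct/defer audit over every
#' encounter: the provisional modality from the effect estimates is
#' assessed against the NIV/HFNC criteria and projected onto the
#' guideline-feasible set.
#'
#' @param encounters encounter table (snapshot fields and flags present).
#' @param ite data.frame from \code{\link{predict.cfrflow}} (columns
#'   encounter_id, p_imv_niv, p_imv_hfnc, modality).
#' @return data.frame with per-encounter model and final modality, audit
#'   status, guideline verdicts, alignment flag and triggering clauses.
#' @export
recommend_cohort <- function(encounters, ite) {
  m <- match(ite$encounter_id, encounters$encounter_id)
  if (anyNA(m)) stopf("ite rows reference unknown encounter ids")
  enc <- encounters[m, ]
  out <- vector("list", nrow(ite))
  for (i in seq_len(nrow(ite))) {
    snap <- snapshot_from_encounter(enc[i, ])
    assess <- assess_guidelines(snap, ite$modality[i])
    fin <- audit_and_project(ite[i, ], assess, snap)
    out[[i]] <- data.frame(
      encounter_id = ite$encounter_id[i],
      model_modality = ite$modality[i],
      p_imv_niv = ite$p_imv_niv[i], p_imv_hfnc = ite$p_imv_hfnc[i],
      niv_recommendation = assess$niv$recommendation,
      hfnc_recommendation = assess$hfnc$recommendation,
      model_alignment = assess$model_alignment$alignment,
      modality = fin$modality, status = fin$status,
      triggering_clauses = paste(fin$triggering_clauses, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Default guideline summary text for prompt bundles
#'
#' @return single character string summarising the NIV indications, HFNC
#'   indications and HFNC first-line blockers encoded by the rule engine.
#' @export
guideline_summary_text <- function() {
  paste(
    "NIV is recommended when any of the following holds: COPD exacerbation",
    "with respiratory acidosis (pH <= 7.35, PaCO2 > 45 mmHg); cardiogenic",
    "pulmonary edema; neuromuscular disease or obesity hypoventilation with",
    "respiratory acidosis; prophylactic post-extubation use in high-risk",
    "patients (not low-risk, not established post-extubation failure);",
    "immunocompromised patients with mild-to-moderate respiratory failure",
    "(conditional). HFNC is recommended for de novo hypoxemic respiratory",
    "failure; post-operative post-extubation high-risk patients; NIV",
    "intolerance with moderate-to-severe failure; moderate-to-severe failure",
    "without an NIV indication; post-operative failure and chest trauma",
    "(both conditional). HFNC is not first line when the patient has acute",
    "hypercapnic respiratory failure (unless NIV is contraindicated or not",
    "tolerated) or when there is a clear guideline indication for NIV.")
}
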