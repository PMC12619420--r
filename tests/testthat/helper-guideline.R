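# Curated snapshot battery covering every guideline clause, both HFNC
# first-line blockers, the acidosis boundary values and unknown-field
# handling. Each case states the expected verdicts.
guideline_battery <- function() list(
  ## --- NIV indications -----------------------------------------------
  list(s = list(ph = 7.28, paco2 = 60, copd_exacerbation = TRUE),
       niv = "Yes", niv_clause = "NIV-1", hfnc = "No"),
  list(s = list(ph = 7.35, paco2 = 46, copd_exacerbation = TRUE),
       niv = "Yes", niv_clause = "NIV-1", hfnc = "No"),   # boundary acidosis
  list(s = list(ph = 7.36, paco2 = 60, spo2 = 97, fio2 = 0.21,
                resp_rate = 18, copd_exacerbation = TRUE),
       niv = "Either", hfnc = "Either"),                  # acidosis absent
  list(s = list(ph = 7.37, paco2 = 40, cardiogenic_pulmonary_edema = TRUE),
       niv = "Yes", niv_clause = "NIV-2", hfnc = "No"),
  list(s = list(ph = 7.30, paco2 = 50, neuromuscular_disease = TRUE),
       niv = "Yes", niv_clause = "NIV-3", hfnc = "No"),
  list(s = list(ph = 7.31, paco2 = 48, obesity_hypoventilation = TRUE),
       niv = "Yes", niv_clause = "NIV-3", hfnc = "No"),
  list(s = list(ph = 7.45, paco2 = 38, spo2 = 96, fio2 = 0.21,
                resp_rate = 16, neuromuscular_disease = TRUE),
       niv = "Either", hfnc = "Either"),
  list(s = list(ph = 7.40, paco2 = 40, post_extubation = TRUE,
                post_extubation_high_risk = TRUE),
       niv = "Yes", niv_clause = "NIV-4"),
  list(s = list(ph = 7.40, paco2 = 40, established_post_extubation_rf = TRUE),
       niv = "No", niv_clause = "NIV-NEG-1"),
  list(s = list(ph = 7.40, paco2 = 40, post_extubation = TRUE),
       niv = "No", niv_clause = "NIV-NEG-2"),             # low-risk prophylaxis
  list(s = list(ph = 7.42, paco2 = 38, spo2 = 90, fio2 = 0.40,
                immunocompromised = TRUE),
       niv = "Yes", niv_clause = "NIV-5", niv_conf = "low"),
  ## --- HFNC indications ----------------------------------------------
  list(s = list(ph = 7.46, paco2 = 34, de_novo_hypoxemic_rf = TRUE),
       niv = "Either", hfnc = "Yes", hfnc_clause = "HFNC-1"),
  list(s = list(ph = 7.41, paco2 = 41, post_operative = TRUE,
                post_extubation_high_risk = TRUE),
       hfnc = "Yes", hfnc_clause = "HFNC-2"),
  list(s = list(ph = 7.44, paco2 = 36, spo2 = 89, fio2 = 0.50,
                niv_intolerant = TRUE),
       hfnc = "Yes", hfnc_clause = "HFNC-3"),             # moderate ARF
  list(s = list(ph = 7.44, paco2 = 36, spo2 = 88, fio2 = 0.60),
       niv = "Either", hfnc = "Yes", hfnc_clause = "HFNC-4"),
  list(s = list(ph = 7.42, paco2 = 38, spo2 = 95, fio2 = 0.30,
                resp_rate = 28, post_operative = TRUE),
       hfnc = "Yes", hfnc_clause = "HFNC-5", hfnc_conf = "low"),
  list(s = list(ph = 7.42, paco2 = 38, spo2 = 96, fio2 = 0.30,
                resp_rate = 26, chest_trauma = TRUE),
       hfnc = "Yes", hfnc_clause = "HFNC-6", hfnc_conf = "low"),
  ## --- HFNC first-line blockers --------------------------------------
  list(s = list(ph = 7.28, paco2 = 60, copd_exacerbation = TRUE),
       hfnc = "No", hfnc_clause = "HFNC-BLOCK-1"),
  list(s = list(ph = 7.30, paco2 = 55),                   # acidosis alone
       hfnc = "No", hfnc_clause = "HFNC-BLOCK-1"),
  list(s = list(ph = 7.37, paco2 = 44, cardiogenic_pulmonary_edema = TRUE),
       hfnc = "No", hfnc_clause = "HFNC-BLOCK-2"),        # clear NIV indication
  list(s = list(ph = 7.28, paco2 = 60, spo2 = 89, fio2 = 0.50,
                copd_exacerbation = TRUE, niv_intolerant = TRUE),
       niv = "Yes", hfnc = "Yes"),                        # blockers waived
  ## contraindicated NIV waives the blockers, but the indication table
  ## only names NIV intolerance, so HFNC stays permissive (Either)
  list(s = list(ph = 7.28, paco2 = 60, spo2 = 89, fio2 = 0.50,
                copd_exacerbation = TRUE, niv_contraindicated = TRUE),
       hfnc = "Either"),
  ## --- boundary / unknown handling -----------------------------------
  list(s = list(ph = 7.35, paco2 = 45, spo2 = 96, fio2 = 0.21,
                resp_rate = 18, copd_exacerbation = TRUE),
       niv = "Either"),                                   # PaCO2 not > 45
  list(s = list(paco2 = 60, copd_exacerbation = TRUE, spo2 = 96,
                fio2 = 0.21, resp_rate = 18),
       niv = "Either", niv_skip = "NIV-1"),               # pH unknown
  list(s = list(ph = 7.42, paco2 = 38, immunocompromised = TRUE),
       niv = "Either", niv_skip = "NIV-5"),               # severity unknown
  list(s = list(ph = 7.40, paco2 = 40, spo2 = 97, fio2 = 0.21,
                resp_rate = 14),
       niv = "Either", hfnc = "Either"),                  # no indication at all
  list(s = list(ph = 7.46, paco2 = 30, spo2 = 85, fio2 = 0.80,
                de_novo_hypoxemic_rf = TRUE, niv_intolerant = TRUE),
       hfnc = "Yes"),
  list(s = list(ph = 7.20, paco2 = 70, copd_exacerbation = TRUE,
                niv_intolerant = TRUE, spo2 = 82, fio2 = 0.70),
       niv = "Yes", hfnc = "Yes"))

## Runs the battery; returns number of cases checked (fails via expect_*)
run_guideline_battery <- function() {
  battery <- guideline_battery()
  for (i in seq_along(battery)) {
    case <- battery[[i]]
    snap <- do.call(clinical_snapshot, case$s)
    niv <- assess_niv(snap)
    hfnc <- assess_hfnc(snap, niv)
    info <- paste("battery case", i)
    if (!is.null(case$niv))
      expect_equal(niv$recommendation, case$niv, info = info)
    if (!is.null(case$niv_clause))
      expect_true(case$niv_clause %in% niv$clause_ids, info = info)
    if (!is.null(case$niv_conf))
      expect_equal(niv$confidence, case$niv_conf, info = info)
    if (!is.null(case$niv_skip))
      expect_true(case$niv_skip %in% niv$skipped_clauses, info = info)
    if (!is.null(case$hfnc))
      expect_equal(hfnc$recommendation, case$hfnc, info = info)
    if (!is.null(case$hfnc_clause))
      expect_true(case$hfnc_clause %in% hfnc$clause_ids, info = info)
    if (!is.null(case$hfnc_conf))
      expect_equal(hfnc$confidence, case$hfnc_conf, info = info)
    if (niv$recommendation != "Either")
      expect_gt(length(niv$clause_ids), 0)
    if (hfnc$recommendation != "Either")
      expect_gt(length(hfnc$clause_ids), 0)
  }
  length(battery)
}

## Exhaustive audit totality sweep; returns the 27-row table
run_audit_totality <- function() {
  rec <- function(r) list(recommendation = r, confidence = "high",
                          explanation = "synthetic",
                          clause_ids = if (r == "Either") character() else "T",
                          skipped_clauses = character())
  rows <- list()
  for (nv in c("Yes", "No", "Either")) for (hv in c("Yes", "No", "Either"))
    for (mo in c("NIV", "HFNC", "Indifferent")) {
      a <- structure(list(niv = rec(nv), hfnc = rec(hv)),
                     class = "guideline_assessment")
      fin <- audit_and_project(list(modality = mo, p_imv_niv = 0.25,
                                    p_imv_hfnc = 0.30), a)
      rows[[length(rows) + 1]] <- data.frame(
        niv = nv, hfnc = hv, model = mo, final = fin$modality,
        status = fin$status, stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}
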