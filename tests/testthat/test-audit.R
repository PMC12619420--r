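mk_assessment <- function(niv, hfnc, niv_skip = character(),
                          hfnc_skip = character()) {
  rec <- function(r, skip) list(recommendation = r,
                                confidence = "high",
                                explanation = "synthetic",
                                clause_ids = if (r == "Either") character()
                                             else "TEST-1",
                                skipped_clauses = skip)
  structure(list(niv = rec(niv, niv_skip), hfnc = rec(hfnc, hfnc_skip)),
            class = "guideline_assessment")
}

mk_ite <- function(modality, p_niv = 0.25, p_hfnc = 0.30) {
  list(modality = modality, p_imv_niv = p_niv, p_imv_hfnc = p_hfnc)
}

test_that("the audit covers all 27 verdict-by-modality combinations", {
  verdicts <- c("Yes", "No", "Either")
  modalities <- c("NIV", "HFNC", "Indifferent")
  n_cases <- 0
  for (nv in verdicts) for (hv in verdicts) for (mo in modalities) {
    a <- mk_assessment(nv, hv)
    fin <- audit_and_project(mk_ite(mo), a)
    n_cases <- n_cases + 1
    expect_true(fin$status %in% c("unchanged", "corrected", "deferred"))
    expect_true(fin$modality %in% modalities)
    expect_gt(length(fin$triggering_clauses), 0)
    ## soundness: a non-deferred final modality is admissible
    if (fin$status != "deferred") {
      adm <- if (fin$modality == "NIV") nv else hv
      expect_true(adm %in% c("Yes", "Either"))
    }
    ## deferral always lands on Indifferent
    if (fin$status == "deferred") expect_equal(fin$modality, "Indifferent")
  }
  expect_equal(n_cases, 27)
})

test_that("the projection rules match the block/correct/defer semantics", {
  ## inadmissible model choice corrected to the admissible alternative
  fin <- audit_and_project(mk_ite("HFNC"), mk_assessment("Yes", "No"))
  expect_equal(fin$modality, "NIV")
  expect_equal(fin$status, "corrected")

  ## admissible model choice passes unchanged
  fin <- audit_and_project(mk_ite("NIV"), mk_assessment("Yes", "Either"))
  expect_equal(fin$modality, "NIV")
  expect_equal(fin$status, "unchanged")

  ## indifferent model, both admissible: lower estimated risk wins
  fin <- audit_and_project(mk_ite("Indifferent", 0.25, 0.30),
                           mk_assessment("Yes", "Yes"))
  expect_equal(fin$modality, "NIV")
  expect_equal(fin$status, "unchanged")
  expect_match(fin$rationale, "lower")
  fin <- audit_and_project(mk_ite("Indifferent", 0.31, 0.30),
                           mk_assessment("Yes", "Yes"))
  expect_equal(fin$modality, "HFNC")

  ## both blocked: defer
  fin <- audit_and_project(mk_ite("NIV"), mk_assessment("No", "No"))
  expect_equal(fin$status, "deferred")
  expect_equal(fin$modality, "Indifferent")
})

test_that("undetermined admissibility (missing data) defers", {
  ## the model's own modality rests on skipped clauses
  a <- mk_assessment("Either", "Yes", niv_skip = "NIV-1")
  fin <- audit_and_project(mk_ite("NIV"), a)
  expect_equal(fin$status, "deferred")

  ## full-engine route: immunocompromised with unknown severity
  snap <- clinical_snapshot(ph = 7.42, paco2 = 38, immunocompromised = TRUE)
  assess <- assess_guidelines(snap, "NIV")
  expect_true("NIV-5" %in% assess$niv$skipped_clauses)
  fin <- audit_and_project(mk_ite("NIV"), assess, snap)
  expect_equal(fin$status, "deferred")
})

test_that("alignment verdicts follow admissibility and exclusivity", {
  expect_true(check_alignment("NIV", mk_assessment("Yes", "No"))$alignment)
  expect_false(check_alignment("HFNC", mk_assessment("Yes", "No"))$alignment)
  expect_true(check_alignment("Indifferent",
                              mk_assessment("Either", "Either"))$alignment)
  expect_false(check_alignment("NIV",
                               mk_assessment("Either", "Yes"))$alignment)
  expect_false(check_alignment("Indifferent",
                               mk_assessment("No", "No"))$alignment)
})

test_that("cohort-level recommendation pipeline is consistent", {
  coh <- small_cohort(n = 80, seed = 31, timeseries = FALSE)
  ite <- data.frame(encounter_id = coh$encounters$encounter_id,
                    p_imv_niv = runif(80, 0.1, 0.5),
                    p_imv_hfnc = runif(80, 0.1, 0.5))
  ite$modality <- classify_ite(ite$p_imv_niv, ite$p_imv_hfnc)
  rec <- recommend_cohort(coh$encounters, ite)
  expect_equal(nrow(rec), 80)
  expect_true(all(rec$status %in% c("unchanged", "corrected", "deferred")))
  expect_true(all(rec$modality %in% c("NIV", "HFNC", "Indifferent")))
  ## deferred recommendations are always Indifferent
  expect_true(all(rec$modality[rec$status == "deferred"] == "Indifferent"))
  expect_true(all(nchar(rec$triggering_clauses) > 0))
})
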