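## Structured document exchange with the recommendation backend. The
## default backend is the rule engine; an external (LLM) backend is an
## interface contract only: it consumes the prompt text and must return
## the same structured JSON document.

.rec_enum <- c("Yes", "No", "Either")
.conf_enum <- c("high", "medium", "low")

#' Render a guideline assessment as the structured output document
#'
#' JSON object with exactly the keys \code{NIV_recommendation},
#' \code{HFNC_recommendation} and \code{Model_alignment}.
#'
#' @param assessment a \code{guideline_assessment}.
#' @return a JSON string (validates against the shipped schema).
#' @export
render_output <- function(assessment) {
  need <- function(x, f) {
    if (is.null(x[[f]]) || length(x[[f]]) == 0 || is.na(x[[f]]))
      stopf("cannot render: missing field '%s'", f)
    x[[f]]
  }
  doc <- list(
    NIV_recommendation = list(
      recommendation = need(assessment$niv, "recommendation"),
      confidence = need(assessment$niv, "confidence"),
      explanation = need(assessment$niv, "explanation")),
    HFNC_recommendation = list(
      recommendation = need(assessment$hfnc, "recommendation"),
      confidence = need(assessment$hfnc, "confidence"),
      explanation = need(assessment$hfnc, "explanation")),
    Model_alignment = list(
      alignment = need(assessment$model_alignment, "alignment"),
      explanation = need(assessment$model_alignment, "explanation")))
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
}

#' Parse and validate a backend response document
#'
#' Strict validation: all three keys must be present, recommendation and
#' confidence values must come from their enumerations, alignment must be
#' boolean. A malformed document yields an error naming the offending key;
#' no partial assessment is ever returned.
#'
#' @param text JSON text as returned by a backend.
#' @return a \code{guideline_assessment}.
#' @export
parse_backend_response <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = TRUE),
                  error = function(e) stopf("malformed JSON: %s",
                                            conditionMessage(e)))
  for (key in c("NIV_recommendation", "HFNC_recommendation",
                "Model_alignment"))
    if (is.null(doc[[key]]))
      stopf("validation failure: missing key '%s'", key)
  get_rec <- function(key) {
    d <- doc[[key]]
    for (f in c("recommendation", "confidence", "explanation"))
      if (is.null(d[[f]])) stopf("validation failure: '%s' lacks '%s'",
                                 key, f)
    if (!d$recommendation %in% .rec_enum)
      stopf("validation failure: '%s' recommendation '%s' not in {%s}",
            key, d$recommendation, paste(.rec_enum, collapse = ", "))
    if (!d$confidence %in% .conf_enum)
      stopf("validation failure: '%s' confidence '%s' not in {%s}",
            key, d$confidence, paste(.conf_enum, collapse = ", "))
    .mk_rec(d$recommendation, d$confidence, character(), character(),
            d$explanation)
  }
  al <- doc$Model_alignment
  if (is.null(al$alignment) || !is.logical(al$alignment))
    stopf("validation failure: 'Model_alignment' alignment must be boolean")
  if (is.null(al$explanation))
    stopf("validation failure: 'Model_alignment' lacks 'explanation'")
  structure(list(niv = get_rec("NIV_recommendation"),
                 hfnc = get_rec("HFNC_recommendation"),
                 model_alignment = list(alignment = al$alignment,
                                        explanation = al$explanation)),
            class = "guideline_assessment")
}

#' Input bundle for the recommendation backend
#'
#' @param guideline_summary text summarising the indication and blocker
#'   criteria for both modalities.
#' @param t0 decision timestamp (hours from admission, or any printable
#'   label).
#' @param model_modality provisional modality from the estimator.
#' @param top_features data.frame (feature, attribution) of the most
#'   influential features.
#' @param recent_parameters named list of the most recent pre-decision
#'   values (pH, PaCO2, respiratory rate, SpO2, FiO2).
#' @param notes character vector of clinical note texts from the 72 h
#'   before the decision (may be empty).
#' @param temperature backend sampling temperature (default 0.1).
#' @param schema_id identifier of the output schema.
#' @return an object of class \code{prompt_bundle}.
#' @export
prompt_bundle <- function(guideline_summary, t0, model_modality,
                          top_features, recent_parameters, notes = character(),
                          temperature = 0.1,
                          schema_id = "guideline_output_v1") {
  structure(list(guideline_summary = guideline_summary, t0 = t0,
                 model_modality = model_modality,
                 top_features = top_features,
                 recent_parameters = recent_parameters, notes = notes,
                 adapter_config = list(temperature = temperature,
                                       schema_id = schema_id)),
            class = "prompt_bundle")
}

#' Deterministic prompt text from a bundle
#'
#' Fixed section order: guideline summary, decision timestamp, model
#' output with its attributed features, recent clinical parameters, notes
#' (with an explicit placeholder when none exist), and the three tasks the
#' backend must perform (concordance assessment, independent
#' recommendation, cited justification).
#'
#' @param bundle a \code{\link{prompt_bundle}}.
#' @return a single character string.
#' @export
build_prompt <- function(bundle) {
  stopifnot(inherits(bundle, "prompt_bundle"))
  feats <- paste(sprintf("- %s (attribution %.5f)",
                         bundle$top_features$feature,
                         bundle$top_features$attribution), collapse = "\n")
  params <- paste(sprintf("- %s: %s", names(bundle$recent_parameters),
                          vapply(bundle$recent_parameters, format, "")),
                  collapse = "\n")
  notes <- if (length(bundle$notes) == 0)
    "No clinical notes available in the 72 h before the decision point."
  else paste(sprintf("NOTE %d:\n%s", seq_along(bundle$notes), bundle$notes),
             collapse = "\n\n")
  paste0(
    "## Clinical guideline summary\n", bundle$guideline_summary, "\n\n",
    "## Decision timestamp (T0)\n", format(bundle$t0), "\n\n",
    "## Model output at T0\nProvisional modality: ", bundle$model_modality,
    "\nTop attributed features:\n", feats, "\n\n",
    "## Recent clinical parameters (pre-T0)\n", params, "\n\n",
    "## Clinical notes (<= 72 h pre-T0)\n", notes, "\n\n",
    "## Tasks\n",
    "1. Assess concordance between the model recommendation and the guideline criteria.\n",
    "2. Issue an independent recommendation: NIV, HFNC, or Indifferent.\n",
    "3. Justify the decision by explicitly citing the relevant guideline statements.\n",
    "Return a JSON object with keys NIV_recommendation, HFNC_recommendation, Model_alignment (schema ",
    bundle$adapter_config$schema_id, "; temperature ",
    format(bundle$adapter_config$temperature), ").\n")
}
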