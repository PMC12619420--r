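{
  "$id": "guideline_output_v1",
  "type": "object",
  "required": ["NIV_recommendation", "HFNC_recommendation", "Model_alignment"],
  "additionalProperties": false,
  "properties": {
    "NIV_recommendation": {
      "type": "object",
      "required": ["recommendation", "confidence", "explanation"],
      "properties": {
        "recommendation": {"enum": ["Yes", "No", "Either"]},
        "confidence": {"enum": ["high", "medium", "low"]},
        "explanation": {"type": "string"}
      }
    },
    "HFNC_recommendation": {
      "type": "object",
      "required": ["recommendation", "confidence", "explanation"],
      "properties": {
        "recommendation": {"enum": ["Yes", "No", "Either"]},
        "confidence": {"enum": ["high", "medium", "low"]},
        "explanation": {"type": "string"}
      }
    },
    "Model_alignment": {
      "type": "object",
      "required": ["alignment", "explanation"],
      "properties": {
        "alignment": {"type": "boolean"},
        "explanation": {"type": "string"}
      }
    }
  }
}
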