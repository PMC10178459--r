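{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "clonocall/case_report/1.0",
  "title": "clonocall case report",
  "type": "object",
  "required": ["schema_version", "case_id", "b_cell_call", "t_cell_call",
               "assay_calls", "run_qc", "model_name", "software"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "case_id": {"type": "string"},
    "b_cell_call": {"enum": ["CLONAL", "NEC", "INVALID", null]},
    "t_cell_call": {"enum": ["CLONAL", "NEC", "INVALID", null]},
    "assay_calls": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sample_id", "target", "call", "fired_rule", "model_name"],
        "properties": {
          "sample_id": {"type": "string"},
          "target": {"enum": ["IGH_FR1", "IGH_FR2", "IGH_FR3", "IGK", "TRG", "TRB"]},
          "call": {"enum": ["CLONAL", "NEC", "INVALID", "OLIGOCLONAL", "POLYCLONAL_MINOR"]},
          "dominant_pcts": {"type": ["array", "number", "null"]},
          "background_pct": {"type": ["number", "null"]},
          "fired_rule": {"type": "string"},
          "model_name": {"type": "string"}
        }
      }
    },
    "run_qc": {
      "type": "object",
      "required": ["run_pass", "q30_pass", "negative_pass", "positive_pass"],
      "properties": {
        "run_pass": {"type": "boolean"},
        "q30_pass": {"type": "boolean"},
        "negative_pass": {"type": "boolean"},
        "positive_pass": {"type": "boolean"},
        "messages": {"type": ["array", "string", "null"]}
      }
    },
    "model_name": {"type": "string"},
    "software": {
      "type": "object",
      "required": ["package", "version"]
    }
  }
}
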