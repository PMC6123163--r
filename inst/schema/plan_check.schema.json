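{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "plancheckminer/plan_check/1.0",
  "title": "Plan-check document",
  "description": "One secondary dose-calculation plan-check: patient demographics, plan/beam parameters, approval stamps, per-target mean doses from the planning system and the independent check, and the 3D gamma pass rate. Doses are total plan doses in Gy; timestamps ISO-8601 UTC.",
  "type": "object",
  "required": ["schema_version", "document_type", "patient_id", "patient_name",
               "patient_sex", "birth_date", "plan_name", "institution",
               "machine", "tps", "approvals", "beams", "targets",
               "gamma_pass_pct", "gamma_criteria", "n_fractions", "created_at"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "document_type": {"const": "plan_check"},
    "patient_id": {"type": "string"},
    "patient_name": {"type": "string"},
    "patient_sex": {"type": "string"},
    "birth_date": {"type": "string", "format": "date"},
    "plan_name": {"type": "string"},
    "institution": {"type": "string"},
    "machine": {"type": "string"},
    "tps": {"type": "string"},
    "approvals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["approver_name", "role", "approved_at"],
        "properties": {
          "approver_name": {"type": "string"},
          "role": {"type": "string"},
          "approved_at": {"type": "string", "format": "date-time"}
        }
      }
    },
    "beams": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["beam_name", "energy_label", "mlc_mode",
                     "gantry_angles", "collimator_angles", "mu"],
        "properties": {
          "beam_name": {"type": "string"},
          "energy_label": {"type": "string"},
          "mlc_mode": {"enum": ["static", "dynamic", "vmat"]},
          "gantry_angles": {"type": "array",
                            "items": {"type": "number",
                                      "minimum": 0, "exclusiveMaximum": 360}},
          "collimator_angles": {"type": "array",
                                "items": {"type": "number",
                                          "minimum": 0,
                                          "exclusiveMaximum": 360}},
          "mu": {"type": "number", "minimum": 0}
        }
      }
    },
    "targets": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["roi_name", "mean_dose_tps", "mean_dose_check"],
        "properties": {
          "roi_name": {"type": "string"},
          "mean_dose_tps": {"type": "number", "exclusiveMinimum": 0},
          "mean_dose_check": {"type": "number", "exclusiveMinimum": 0},
          "coverage_90_pct": {"type": ["number", "null"],
                              "minimum": 0, "maximum": 100}
        }
      }
    },
    "gamma_pass_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "gamma_criteria": {"type": "string"},
    "n_fractions": {"type": "integer", "minimum": 1},
    "notes": {"type": "string"},
    "created_at": {"type": "string", "format": "date-time"}
  }
}
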