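{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "plancheckminer/dvh/1.0",
  "title": "DVH document",
  "description": "Per-structure cumulative dose-volume curves from the planning system ('tps') and the independent check ('check'), linked to the plan-check document of the same patient plan by patient_id + plan_name. Volumes are percent of structure volume; curves start at 100% at 0 Gy and are non-increasing.",
  "type": "object",
  "required": ["schema_version", "document_type", "patient_id", "plan_name",
               "n_fractions", "structures"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "document_type": {"const": "dvh"},
    "patient_id": {"type": "string"},
    "plan_name": {"type": "string"},
    "n_fractions": {"type": "integer", "minimum": 1},
    "structures": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["roi_name", "tps_roi_name", "curves"],
        "properties": {
          "roi_name": {"type": "string",
                       "description": "canonical name assigned by the check system"},
          "tps_roi_name": {"type": "string",
                           "description": "original planner-typed name, searchable"},
          "curves": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["source", "dose_gy", "volume_pct"],
              "properties": {
                "source": {"enum": ["tps", "check"]},
                "dose_gy": {"type": "array", "minItems": 2,
                            "items": {"type": "number", "minimum": 0},
                            "description": "strictly increasing, starts at 0"},
                "volume_pct": {"type": "array", "minItems": 2,
                               "items": {"type": "number",
                                         "minimum": 0, "maximum": 100},
                               "description": "non-increasing, first value 100"}
              }
            }
          },
          "constraints": {
            "type": "array",
            "items": {
              "type": "object",
              "anyOf": [{"required": ["volume_pct"]},
                        {"required": ["dose_gy"]}],
              "properties": {
                "volume_pct": {"type": ["number", "null"],
                               "minimum": 0, "maximum": 100},
                "dose_gy": {"type": ["number", "null"], "minimum": 0},
                "achieved_value": {"type": "number"},
                "result": {"enum": ["pass", "warn", "fail"]}
              }
            }
          }
        }
      }
    }
  }
}
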