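{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Squat set score report",
  "type": "object",
  "required": ["set", "rounds", "volume_envelope"],
  "properties": {
    "set": {
      "type": "object",
      "required": ["n_rounds", "round_duration", "sum_index1",
                   "sum_index2", "sum_index3", "grand_total"],
      "properties": {
        "n_rounds": {"type": "integer", "minimum": 1},
        "round_duration": {"type": "number", "exclusiveMinimum": 0},
        "sum_index1": {"type": "integer", "minimum": 0},
        "sum_index2": {"type": "integer", "minimum": 0},
        "sum_index3": {"type": "integer", "minimum": 0},
        "grand_total": {"type": "integer", "minimum": 0}
      }
    },
    "rounds": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["round", "index1", "index2", "index3", "total"],
        "properties": {
          "round": {"type": "integer", "minimum": 1},
          "index1": {"type": "integer", "minimum": 0, "maximum": 3},
          "index2": {"type": "integer", "minimum": 0, "maximum": 3},
          "index3": {"type": "integer", "minimum": 0, "maximum": 4},
          "total": {"type": "integer", "minimum": 0, "maximum": 10},
          "empty": {"type": "boolean"},
          "diagnostics": {"type": "object"}
        }
      }
    },
    "volume_envelope": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["round", "bgm_pct", "noise_pct"],
        "properties": {
          "round": {"type": "integer", "minimum": 1},
          "bgm_pct": {"type": "number", "minimum": 0, "maximum": 100},
          "noise_pct": {"type": "number", "minimum": 0, "maximum": 100}
        }
      }
    }
  }
}
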