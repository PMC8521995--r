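{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Survey cohort summary",
  "type": "object",
  "required": ["n", "table"],
  "properties": {
    "n": {"type": "object", "additionalProperties": {"type": "integer"}},
    "age": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["group", "n"],
        "properties": {
          "group": {"enum": ["younger", "middle", "older", "all"]},
          "n": {"type": "integer", "minimum": 0},
          "mean": {"type": ["number", "null"]},
          "sd": {"type": ["number", "null"]},
          "min": {"type": ["number", "null"]},
          "max": {"type": ["number", "null"]}
        }
      }
    },
    "table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["group", "variable", "category", "n", "pct"],
        "properties": {
          "group": {"enum": ["younger", "middle", "older", "all"]},
          "variable": {"enum": ["gender", "exercise_change", "habit"]},
          "category": {"type": "string"},
          "n": {"type": "integer", "minimum": 0},
          "pct": {"type": ["number", "null"]}
        }
      }
    }
  }
}
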