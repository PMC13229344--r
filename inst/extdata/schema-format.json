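{
  "$comment": "Schema-of-schemas: the expected shape of a population schema file.",
  "type": "object",
  "required": ["attributes", "relationships"],
  "properties": {
    "attributes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "kind", "level"],
        "properties": {
          "name": {"type": "string"},
          "kind": {"enum": ["integer", "categorical"]},
          "level": {"enum": ["person", "household"]},
          "min": {"type": "integer"},
          "max": {"type": "integer"},
          "categories": {"type": "array", "items": {"type": "string"}, "minItems": 2}
        }
      },
      "$comment": "Exactly one attribute must be named 'age', of kind integer with a bounded min/max."
    },
    "relationships": {
      "type": "array",
      "items": {"type": "string"},
      "$comment": "Allowed role labels; must contain 'head'."
    }
  }
}
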