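{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Rule-set configuration",
  "type": "object",
  "required": ["rulesets"],
  "properties": {
    "version": {"type": "string"},
    "rulesets": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["event_type", "rules"],
        "properties": {
          "event_type": {
            "enum": ["protein-protein-binding", "protein-nucleic-acid-binding",
                     "activation", "inhibition", "induction", "repression",
                     "transport"]
          },
          "source": {
            "enum": ["verbatim", "reconstructed"],
            "description": "Provenance marker: the induction set is shipped verbatim; the other six are template reconstructions."
          },
          "rules": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["id", "condition", "points_if_true", "points_if_false"],
              "properties": {
                "id": {"type": "string"},
                "condition": {
                  "enum": ["actor_is_a", "target_is_a", "actor_has_function",
                           "location_is", "relation_is", "negated_in_kb",
                           "evidence_is"]
                },
                "args": {"type": "array", "items": {"type": "string"}},
                "points_if_true": {"type": "integer"},
                "points_if_false": {"type": "integer"}
              }
            }
          }
        }
      }
    }
  }
}
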