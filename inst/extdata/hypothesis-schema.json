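{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Hypothesis document",
  "description": "A hypothesis is a tree whose leaves are hypothesized molecular events and whose internal nodes are n-ary AND/OR/XOR operators with at least two children.",
  "type": "object",
  "required": ["root"],
  "properties": {
    "id": {"type": "string"},
    "title": {"type": "string"},
    "root": {"$ref": "#/definitions/node"}
  },
  "definitions": {
    "node": {
      "oneOf": [
        {
          "type": "object",
          "required": ["event"],
          "properties": {"event": {"$ref": "#/definitions/event"}},
          "additionalProperties": false
        },
        {
          "type": "object",
          "required": ["operator", "children"],
          "properties": {
            "operator": {"enum": ["AND", "OR", "XOR"]},
            "children": {
              "type": "array",
              "minItems": 2,
              "items": {"$ref": "#/definitions/node"}
            }
          },
          "additionalProperties": false
        }
      ]
    },
    "event": {
      "type": "object",
      "required": ["event_type", "relation", "actor", "target"],
      "properties": {
        "label": {"type": "string"},
        "event_type": {
          "enum": ["protein-protein-binding", "protein-nucleic-acid-binding",
                   "activation", "inhibition", "induction", "repression",
                   "transport"]
        },
        "relation": {"type": "string"},
        "actor": {"$ref": "#/definitions/entity_ref"},
        "target": {"$ref": "#/definitions/entity_ref"},
        "location": {"type": "string", "description": "GO CURIE"},
        "context": {"type": "string", "default": "wt"},
        "negated_claim": {"type": "boolean", "default": false}
      }
    },
    "entity_ref": {
      "type": "object",
      "description": "Exactly one of: instance (entity CURIE), type (ontology CURIE restriction), variable (unbound query variable, optionally with a type restriction).",
      "properties": {
        "instance": {"type": "string"},
        "type": {"type": "string"},
        "variable": {"type": "string", "pattern": "^\\?"}
      },
      "minProperties": 1
    }
  }
}
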