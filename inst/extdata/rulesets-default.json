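{
  "version": "default-1.0",
  "rulesets": [
    {
      "event_type": "induction",
      "source": "verbatim",
      "rules": [
        {"id": "actor-type", "condition": "actor_is_a", "args": ["chebi:36080", "chebi:33697"], "points_if_true": 1, "points_if_false": -1},
        {"id": "target-type", "condition": "target_is_a", "args": ["so:0000236"], "points_if_true": 1, "points_if_false": -1},
        {"id": "actor-function", "condition": "actor_has_function", "args": ["go:0003702"], "points_if_true": 1, "points_if_false": 0},
        {"id": "location", "condition": "location_is", "args": ["go:0005634"], "points_if_true": 1, "points_if_false": -1},
        {"id": "relation", "condition": "relation_is", "args": ["induce"], "points_if_true": 1, "points_if_false": -1},
        {"id": "negation", "condition": "negated_in_kb", "args": [], "points_if_true": 0, "points_if_false": -2}
      ]
    },
    {
      "event_type": "repression",
      "source": "reconstructed",
      "rules": [
        {"id": "actor-type", "condition": "actor_is_a", "args": ["chebi:36080", "chebi:33697"], "points_if_true": 1, "points_if_false": -1},
        {"id": "target-type", "condition": "target_is_a", "args": ["so:0000236"], "points_if_true": 1, "points_if_false": -1},
        {"id": "actor-function", "condition": "actor_has_function", "args": ["go:0016564"], "points_if_true": 1, "points_if_false": 0},
        {"id": "location", "condition": "location_is", "args": ["go:0005634"], "points_if_true": 1, "points_if_false": -1},
        {"id": "relation", "condition": "relation_is", "args": ["repress"], "points_if_true": 1, "points_if_false": -1},
        {"id": "negation", "condition": "negated_in_kb", "args": [], "points_if_true": 0, "points_if_false": -2}
      ]
    },
    {
      "event_type": "activation",
      "source": "reconstructed",
      "rules": [
        {"id": "actor-type", "condition": "actor_is_a", "args": ["chebi:36080", "chebi:33697"], "points_if_true": 1, "points_if_false": -1},
        {"id": "target-type", "condition": "target_is_a", "args": ["chebi:36080", "chebi:33697"], "points_if_true": 1, "points_if_false": -1},
        {"id": "actor-function", "condition": "actor_has_function", "args": ["go:0030234"], "points_if_true": 1, "points_if_false": 0},
        {"id": "location", "condition": "location_is", "args": ["go:0005622"], "points_if_true": 1, "points_if_false": -1},
        {"id": "relation", "condition": "relation_is", "args": ["activate"], "points_if_true": 1, "points_if_false": -1},
        {"id": "negation", "condition": "negated_in_kb", "args": [], "points_if_true": 0, "points_if_false": -2}
      ]
    },
    {
      "event_type": "inhibition",
      "source": "reconstructed",
      "rules": [
        {"id": "actor-type", "condition": "actor_is_a", "args": ["chebi:36080", "chebi:33697"], "points_if_true": 1, "points_if_false": -1},
        {"id": "target-type", "condition": "target_is_a", "args": ["chebi:36080", "chebi:33697"], "points_if_true": 1, "points_if_false": -1},
        {"id": "actor-function", "condition": "actor_has_function", "args": ["go:0004857"], "points_if_true": 1, "points_if_false": 0},
        {"id": "location", "condition": "location_is", "args": ["go:0005622"], "points_if_true": 1, "points_if_false": -1},
        {"id": "relation", "condition": "relation_is", "args": ["inhibit"], "points_if_true": 1, "points_if_false": -1},
        {"id": "negation", "condition": "negated_in_kb", "args": [], "points_if_true": 0, "points_if_false": -2}
      ]
    },
    {
      "event_type": "protein-protein-binding",
      "source": "reconstructed",
      "rules": [
        {"id": "actor-type", "condition": "actor_is_a", "args": ["chebi:36080"], "points_if_true": 1, "points_if_false": -1},
        {"id": "target-type", "condition": "target_is_a", "args": ["chebi:36080"], "points_if_true": 1, "points_if_false": -1},
        {"id": "actor-function", "condition": "actor_has_function", "args": ["go:0005515"], "points_if_true": 1, "points_if_false": 0},
        {"id": "location", "condition": "location_is", "args": ["go:0005622"], "points_if_true": 1, "points_if_false": -1},
        {"id": "relation", "condition": "relation_is", "args": ["bind"], "points_if_true": 1, "points_if_false": -1},
        {"id": "negation", "condition": "negated_in_kb", "args": [], "points_if_true": 0, "points_if_false": -2}
      ]
    },
    {
      "event_type": "protein-nucleic-acid-binding",
      "source": "reconstructed",
      "rules": [
        {"id": "actor-type", "condition": "actor_is_a", "args": ["chebi:36080"], "points_if_true": 1, "points_if_false": -1},
        {"id": "target-type", "condition": "target_is_a", "args": ["so:0000110"], "points_if_true": 1, "points_if_false": -1},
        {"id": "actor-function", "condition": "actor_has_function", "args": ["go:0003677"], "points_if_true": 1, "points_if_false": 0},
        {"id": "location", "condition": "location_is", "args": ["go:0005634"], "points_if_true": 1, "points_if_false": -1},
        {"id": "relation", "condition": "relation_is", "args": ["bind"], "points_if_true": 1, "points_if_false": -1},
        {"id": "negation", "condition": "negated_in_kb", "args": [], "points_if_true": 0, "points_if_false": -2}
      ]
    },
    {
      "event_type": "transport",
      "source": "reconstructed",
      "rules": [
        {"id": "actor-type", "condition": "actor_is_a", "args": ["chebi:36080", "chebi:33697"], "points_if_true": 1, "points_if_false": -1},
        {"id": "target-type", "condition": "target_is_a", "args": ["chebi:24431"], "points_if_true": 1, "points_if_false": -1},
        {"id": "actor-function", "condition": "actor_has_function", "args": ["go:0005215"], "points_if_true": 1, "points_if_false": 0},
        {"id": "location", "condition": "location_is", "args": ["go:0016020"], "points_if_true": 1, "points_if_false": -1},
        {"id": "relation", "condition": "relation_is", "args": ["transport"], "points_if_true": 1, "points_if_false": -1},
        {"id": "negation", "condition": "negated_in_kb", "args": [], "points_if_true": 0, "points_if_false": -2}
      ]
    }
  ]
}
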