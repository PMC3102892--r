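{
  "id": "hqd:hypothesis-gal-induction",
  "title": "Induction of GAL gene expression by Gal3p, Gal4p and Gal80p",
  "root": {
    "operator": "OR",
    "children": [
      {
        "event": {
          "label": "e1",
          "event_type": "induction",
          "relation": "induce",
          "actor": {"instance": "sgd:Gal4p"},
          "target": {"instance": "sgd:GAL1"},
          "location": "go:0005634",
          "context": "wt"
        }
      },
      {
        "operator": "AND",
        "children": [
          {
            "event": {
              "label": "e2",
              "event_type": "induction",
              "relation": "induce",
              "actor": {"instance": "sgd:Gal3p"},
              "target": {"instance": "sgd:GAL2"},
              "location": "go:0005634",
              "context": "wt"
            }
          },
          {
            "event": {
              "label": "e3",
              "event_type": "induction",
              "relation": "induce",
              "actor": {"instance": "sgd:Gal4p"},
              "target": {"instance": "sgd:GAL7"},
              "location": "go:0005634",
              "context": "wt"
            }
          }
        ]
      },
      {
        "operator": "AND",
        "children": [
          {
            "event": {
              "label": "e4",
              "event_type": "induction",
              "relation": "induce",
              "actor": {"instance": "sgd:Gal4p"},
              "target": {"instance": "sgd:GAL7"},
              "location": "go:0005634",
              "context": "wt"
            }
          },
          {
            "event": {
              "label": "e5",
              "event_type": "inhibition",
              "relation": "inhibit",
              "actor": {"instance": "sgd:Gal80p"},
              "target": {"instance": "sgd:Gal4p"},
              "context": "GAL3 over-expressed"
            }
          },
          {
            "event": {
              "label": "e6",
              "event_type": "induction",
              "relation": "induce",
              "actor": {"instance": "sgd:Gal80p"},
              "target": {"instance": "sgd:GAL7"},
              "location": "go:0005634",
              "context": "wt"
            }
          }
        ]
      }
    ]
  }
}
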