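{
  "id": "hqd:hypothesis-gal-transport",
  "title": "Gal2p transports galactose into the cell",
  "root": {
    "event": {
      "label": "e1",
      "event_type": "transport",
      "relation": "transport",
      "actor": {"instance": "sgd:Gal2p"},
      "target": {"instance": "chebi:28260"},
      "location": "go:0016020",
      "context": "wt"
    }
  }
}
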