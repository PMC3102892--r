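{
  "sgd": "http://bio2rdf.org/sgd:",
  "chebi": "http://bio2rdf.org/chebi:",
  "go": "http://bio2rdf.org/go:",
  "so": "http://bio2rdf.org/so:",
  "eco": "http://bio2rdf.org/eco:",
  "hkb": "http://bio2rdf.org/hkb:",
  "rkb": "http://bio2rdf.org/rkb:",
  "hq": "http://bio2rdf.org/hq:",
  "hqd": "http://bio2rdf.org/hqD:"
}
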