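fact_id	event_type	relation	actor	target	location	context	evidence	negated	source
hkb:f01	induction	induce	sgd:Gal4p	sgd:GAL1	go:0005634	wt		false	hkb:src-curated-gal
hkb:f02	induction	induce	sgd:Gal3p	sgd:GAL2	go:0005634	wt		false	hkb:src-curated-gal
hkb:f03	induction	induce	sgd:Gal4p	sgd:GAL7	go:0005634	wt		false	hkb:src-curated-gal
hkb:f04	induction	induce	sgd:Gal80p	sgd:GAL7	go:0005634	wt		false	hkb:src-curated-gal
hkb:f05	inhibition	inhibit	sgd:Gal80p	sgd:Gal4p	go:0005622	wt		false	hkb:src-curated-gal
hkb:f06	transport	transport	sgd:Gal2p	chebi:28260	go:0016020	wt		false	hkb:src-curated-gal
hkb:f07	protein-nucleic-acid-binding	bind	sgd:Mig1p	sgd:GAL1	go:0005634	wt		false	hkb:src-promoter-assay
hkb:f08	protein-nucleic-acid-binding	bind	sgd:Spt15p	sgd:GAL1	go:0005634	wt	eco:0000008	false	hkb:src-promoter-assay
hkb:f09	protein-nucleic-acid-binding	bind	sgd:Gal4p	sgd:GAL1	go:0005634	wt		false	hkb:src-promoter-assay
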