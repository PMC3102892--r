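id	name	types	functions	same_as
sgd:Gal4p	Gal4p	chebi:36080	go:0003677	sgd:S000006169gp
sgd:Gal3p	Gal3p	chebi:36080
sgd:Gal80p	Gal80p	chebi:36080
sgd:Gal2p	Gal2p	chebi:36080	go:0005215
sgd:Mig1p	Mig1p	chebi:36080	go:0003677
sgd:Spt15p	Spt15p	chebi:36080	go:0003677
sgd:GAL1	GAL1	so:0000236
sgd:GAL2	GAL2	so:0000236
sgd:GAL3	GAL3	so:0000236
sgd:GAL4	GAL4	so:0000236
sgd:GAL7	GAL7	so:0000236
sgd:GAL80	GAL80	so:0000236
chebi:28260	galactose	chebi:28260
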