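id	label	parents	part_of
chebi:24431	chemical entity
chebi:23367	molecular entity	chebi:24431
chebi:36080	protein	chebi:23367
chebi:33697	RNA	chebi:23367
chebi:33699	messenger RNA	chebi:33697
chebi:16646	carbohydrate	chebi:23367
chebi:28260	galactose	chebi:16646
so:0000110	sequence feature
so:0000236	gene	so:0000110
go:0003674	molecular function
go:0003702	transcription factor activity	go:0003674
go:0003677	DNA binding	go:0003674
go:0005515	protein binding	go:0003674
go:0005215	transporter activity	go:0003674
go:0016564	transcription repressor activity	go:0003674
go:0030234	enzyme regulator activity	go:0003674
go:0004857	enzyme inhibitor activity	go:0030234
go:0005575	cellular component
go:0005622	intracellular	go:0005575
go:0005634	nucleus	go:0005575	go:0005622
go:0016020	membrane	go:0005575
eco:0000000	evidence
eco:0000006	experimental evidence	eco:0000000
eco:0000008	curated database annotation	eco:0000000
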