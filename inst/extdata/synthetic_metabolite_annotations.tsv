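name	kegg_compound	pathways
L-aspartic acid	C00049	map00250|Alanine, aspartate and glutamate metabolism;map00260|Glycine, serine and threonine metabolism
calystegine B2	C10850	map00960|Tropane, piperidine and pyridine alkaloid biosynthesis
D/L-pyroglutamic acid	C01879	map00330|Arginine and proline metabolism;map00480|Glutathione metabolism
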