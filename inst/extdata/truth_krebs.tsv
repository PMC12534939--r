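# Curated truth alignments for consecutive pathway transformations.
# Reconstruction (not a copy of any published dataset): gapped strings
# are the maximal in-order element-identical correspondence between the
# canonical atom-token strings of the two metabolites (no mismatch
# columns; additions/removals of the transformation appear as gaps),
# reviewed against the known chemistry of each step.
id_a	id_b	gapped_a	gapped_b
oxaloacetate	citrate	OCO-CC-O-C-OO	OCOCCCOOCCOOO
citrate	isocitrate	OCO-CCC-OOCCOOO	OCOCCCCOOO-C-OO
isocitrate	alpha_ketoglutarate	OCOCCCCOOOCOO	OCO-CCC--OCOO
alpha_ketoglutarate	succinate	OCOCCCOCOO	OCO-CC-COO
succinate	fumarate	OCOCCCOO	OCOCCCOO
fumarate	malate	OCOCCC-OO	OCOCCCOOO
malate	oxaloacetate	OCOCC-COOO	OCOCCOC-OO
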