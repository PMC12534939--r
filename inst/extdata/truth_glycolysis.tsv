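# Curated truth alignments for consecutive pathway transformations.
# Reconstruction (not a copy of any published dataset): gapped strings
# are the maximal in-order element-identical correspondence between the
# canonical atom-token strings of the two metabolites (no mismatch
# columns; additions/removals of the transformation appear as gaps),
# reviewed against the known chemistry of each step.
id_a	id_b	gapped_a	gapped_b
glucose	glucose_6_phosphate	--OCC---OCOCCCOOO	OCOCCOPOO-OCCCOOO
glucose_6_phosphate	fructose_6_phosphate	O-C-O-CCOPO-O-OCCCOOO	OCCOOCCCO-OCOP----OOO
fructose_6_phosphate	fructose_1_6_bisphosphate	O-CC----OOCCCOOCOPOOO	OCCCOPOOOO-CCOOCOPOOO
fructose_1_6_bisphosphate	glyceraldehyde_3_phosphate	OCCCOPOOOOCCOOCOPOOO	OCCCOP---------O-OOO
glyceraldehyde_3_phosphate	bisphosphoglycerate_1_3	OCCCOP----O-OOO	OCCCOPOOOOOPOOO
bisphosphoglycerate_1_3	phosphoglycerate_3	OC-CCOPOOOOOPOOO	OCOCCOP----O-OOO
phosphoglycerate_3	phosphoglycerate_2	OCOCC--OPOOOO	OC-CCOOOP-OOO
phosphoglycerate_2	phosphoenolpyruvate	OC-CCOOOPOOO	OCOCC--OPOOO
phosphoenolpyruvate	pyruvate	OCOC-COPOOO	OCOCOC-----
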