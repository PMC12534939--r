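# Glycolysis, ten metabolites from glucose to pyruvate.
# Provenance: reconstructed from standard textbook structures (neutral
# protonation, no stereo descriptors); synthetic fixture, not a database
# export.
order	id	smiles
1	glucose	OCC1OC(O)C(O)C(O)C1O
2	glucose_6_phosphate	OC1OC(COP(=O)(O)O)C(O)C(O)C1O
3	fructose_6_phosphate	OCC1(O)OC(COP(=O)(O)O)C(O)C1O
4	fructose_1_6_bisphosphate	OP(=O)(O)OCC1(O)OC(COP(=O)(O)O)C(O)C1O
5	glyceraldehyde_3_phosphate	O=CC(O)COP(=O)(O)O
6	bisphosphoglycerate_1_3	O=C(OP(=O)(O)O)C(O)COP(=O)(O)O
7	phosphoglycerate_3	OC(=O)C(O)COP(=O)(O)O
8	phosphoglycerate_2	OC(=O)C(OP(=O)(O)O)CO
9	phosphoenolpyruvate	OC(=O)C(=C)OP(=O)(O)O
10	pyruvate	CC(=O)C(=O)O
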