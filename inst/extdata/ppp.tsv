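# Pentose phosphate pathway, eight metabolites treated as a cycle
# (oxidative branch followed by the non-oxidative sugar shuffle back to
# fructose 6-phosphate, which isomerizes to glucose 6-phosphate).
# Provenance: reconstructed from standard textbook structures (neutral
# protonation, no stereo descriptors); synthetic fixture, not a database
# export.
order	id	smiles
1	glucose_6_phosphate	OC1OC(COP(=O)(O)O)C(O)C(O)C1O
2	phosphogluconate_6	OC(=O)C(O)C(O)C(O)C(O)COP(=O)(O)O
3	ribulose_5_phosphate	OCC(=O)C(O)C(O)COP(=O)(O)O
4	ribose_5_phosphate	O=CC(O)C(O)C(O)COP(=O)(O)O
5	sedoheptulose_7_phosphate	OCC(=O)C(O)C(O)C(O)C(O)COP(=O)(O)O
6	glyceraldehyde_3_phosphate	O=CC(O)COP(=O)(O)O
7	erythrose_4_phosphate	O=CC(O)C(O)COP(=O)(O)O
8	fructose_6_phosphate	OCC1(O)OC(COP(=O)(O)O)C(O)C1O
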