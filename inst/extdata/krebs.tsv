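# Krebs cycle (citric acid cycle), seven primary metabolites in cycle
# order starting at oxaloacetate; coenzymes and succinyl-CoA excluded.
# Provenance: reconstructed from standard textbook structures (neutral
# protonation, no stereo descriptors); synthetic fixture, not a database
# export.
order	id	smiles
1	oxaloacetate	OC(=O)CC(=O)C(=O)O
2	citrate	OC(=O)CC(O)(CC(=O)O)C(=O)O
3	isocitrate	OC(=O)C(O)C(CC(=O)O)C(=O)O
4	alpha_ketoglutarate	OC(=O)CCC(=O)C(=O)O
5	succinate	OC(=O)CCC(=O)O
6	fumarate	OC(=O)C=CC(=O)O
7	malate	OC(=O)CC(O)C(=O)O
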