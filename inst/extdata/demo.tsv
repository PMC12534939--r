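# Small common molecules for examples and tests.
# Provenance: elementary textbook structures; synthetic fixture.
order	id	smiles
1	water	O
2	methanol	CO
3	ethanol	CCO
4	acetic_acid	CC(=O)O
5	acetone	CC(=O)C
6	glycine	NCC(=O)O
7	benzene	c1ccccc1
8	pyridine	c1ccncc1
9	dimethyl_sulfide	CSC
10	ethene	C=C
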