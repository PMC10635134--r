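# Synthetic 28-peak table emulating the KG-279 cavity NOE list:
# 3 peaks land on two-carbon ambiguous Leu methyl pairs.
ligand_group	receptor_residue	receptor_group	class
H2	396	I396d1	strong
H2	396	I396g2	medium
H2	408	L408d1	medium
H2	415	V415g1	weak
H2	423	L423d1	weak
H2	425	V425g1	medium
H2	457	I457d1	strong
H4	396	I396d1	medium
H4	408	L408d2	weak
H4	415	V415g2	medium
H4	423	L423dd	weak
H4	425	V425g2	weak
H4	457	I457d1	medium
H4	458	I458g2	weak
H6	396	I396g2	weak
H6	408	L408d1	strong
H6	415	V415g1	medium
H6	423	L423d1	medium
H6	425	V425g1	weak
H6	457	I457d1	weak
H6	408	L408dd	weak
H7	396	I396d1	weak
H7	415	V415g2	weak
H7	423	L423dd	medium
H7	425	V425g1	medium
H7	457	I457d1	weak
H7	458	I458g2	weak
H7	408	L408d2	medium
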