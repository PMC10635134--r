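# Synthetic 12-peak table emulating the KG-655 cavity NOE list:
# 7 peaks involve the degenerate H2/H6 pair (2 distinct heavy atoms each).
ligand_group	receptor_residue	receptor_group	class
H2H6	396	I396d1	strong
H2H6	408	L408d1	medium
H2H6	415	V415g1	medium
H2H6	418	L418d1	strong
H2H6	423	L423d1	weak
H2H6	425	V425g1	medium
H2H6	457	I457d1	weak
H4	396	I396g2	medium
H4	418	L418d2	weak
HO	457	I457d1	medium
H4	458	I458g2	weak
HO	381	V381g1	weak
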