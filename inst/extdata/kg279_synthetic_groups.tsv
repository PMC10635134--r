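# Synthetic stand-in for the KG-279 restraint list (5-chloro-1,3-benzodioxole):
# the two C2 methylene protons share one carbon; three receptor groups are
# unresolved Leu delta-methyl pairs spanning two distinct carbons.
id	owner	residue	protons	heavies
H2	ligand	NA	H2A,H2B	C2,C2
H4	ligand	NA	H4	C4
H6	ligand	NA	H6	C6
H7	ligand	NA	H7	C7
I396d1	receptor	396	HD11,HD12,HD13	CD1,CD1,CD1
I396g2	receptor	396	HG21,HG22,HG23	CG2,CG2,CG2
L408d1	receptor	408	HD11,HD12,HD13	CD1,CD1,CD1
L408d2	receptor	408	HD21,HD22,HD23	CD2,CD2,CD2
L408dd	receptor	408	HD11,HD21	CD1,CD2
V415g1	receptor	415	HG11,HG12,HG13	CG1,CG1,CG1
V415g2	receptor	415	HG21,HG22,HG23	CG2,CG2,CG2
L423d1	receptor	423	HD11,HD12,HD13	CD1,CD1,CD1
L423dd	receptor	423	HD11,HD21	CD1,CD2
V425g1	receptor	425	HG11,HG12,HG13	CG1,CG1,CG1
V425g2	receptor	425	HG21,HG22,HG23	CG2,CG2,CG2
I457d1	receptor	457	HD11,HD12,HD13	CD1,CD1,CD1
I458g2	receptor	458	HG21,HG22,HG23	CG2,CG2,CG2
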