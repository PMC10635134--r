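# Synthetic stand-in for the KG-655 restraint list (3,5-bis(trifluoromethyl)phenol):
# the H2/H6 aromatic pair is chemically equivalent (two distinct ring carbons);
# receptor methyl groups collapse to their single methyl carbon.
id	owner	residue	protons	heavies
H2H6	ligand	NA	H2,H6	C2,C6
H4	ligand	NA	H4	C4
HO	ligand	NA	HO	O1
I396d1	receptor	396	HD11,HD12,HD13	CD1,CD1,CD1
I396g2	receptor	396	HG21,HG22,HG23	CG2,CG2,CG2
L408d1	receptor	408	HD11,HD12,HD13	CD1,CD1,CD1
V415g1	receptor	415	HG11,HG12,HG13	CG1,CG1,CG1
L418d1	receptor	418	HD11,HD12,HD13	CD1,CD1,CD1
L418d2	receptor	418	HD21,HD22,HD23	CD2,CD2,CD2
L423d1	receptor	423	HD11,HD12,HD13	CD1,CD1,CD1
V425g1	receptor	425	HG11,HG12,HG13	CG1,CG1,CG1
I457d1	receptor	457	HD11,HD12,HD13	CD1,CD1,CD1
I458g2	receptor	458	HG21,HG22,HG23	CG2,CG2,CG2
V381g1	receptor	381	HG11,HG12,HG13	CG1,CG1,CG1
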