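res_type	block_atoms	block_masses	chi1_atoms
ARG	NE,CZ,NH1,NH2	14.007,12.011,14.007,14.007	N,CA,CB,CG
ASN	CG,OD1,ND2	12.011,15.999,14.007	N,CA,CB,CG
ASP	CG,OD1,OD2	12.011,15.999,15.999	N,CA,CB,CG
CYS	SG	32.060	N,CA,CB,SG
GLN	CD,OE1,NE2	12.011,15.999,14.007	N,CA,CB,CG
GLU	CD,OE1,OE2	12.011,15.999,15.999	N,CA,CB,CG
HIS	CG,ND1,CD2,CE1,NE2	12.011,14.007,12.011,12.011,14.007	N,CA,CB,CG
ILE	CD1	12.011	N,CA,CB,CG1
LEU	CD1,CD2	12.011,12.011	N,CA,CB,CG
LYS	CE,NZ	12.011,14.007	N,CA,CB,CG
MET	SD,CE	32.060,12.011	N,CA,CB,CG
PHE	CG,CD1,CD2,CE1,CE2,CZ	12.011,12.011,12.011,12.011,12.011,12.011	N,CA,CB,CG
PRO	CG,CD	12.011,12.011	N,CA,CB,CG
SER	OG	15.999	N,CA,CB,OG
THR	OG1,CG2	15.999,12.011	N,CA,CB,OG1
TRP	CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2	12.011,12.011,12.011,14.007,12.011,12.011,12.011,12.011,12.011	N,CA,CB,CG
TYR	OH	15.999	N,CA,CB,CG
VAL	CG1,CG2	12.011,12.011	N,CA,CB,CG1
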