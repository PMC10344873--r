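# Ideal internal coordinates for side-chain heavy atoms.
# Atom is placed bonded to p3 with the given bond length (A), angle
# p2-p3-atom (degrees) and torsion p1-p2-p3-atom (degrees).
# dih = "chi1".."chi4" means torsion = chi_k + offset; "fixed" means offset.
restype	atom	p1	p2	p3	bond	angle	dih	offset
ALA	CB	C	N	CA	1.53	110.4	fixed	-122.5
SER	CB	C	N	CA	1.53	110.4	fixed	-122.5
SER	OG	N	CA	CB	1.42	110.8	chi1	0
CYS	CB	C	N	CA	1.53	110.4	fixed	-122.5
CYS	SG	N	CA	CB	1.81	114.4	chi1	0
THR	CB	C	N	CA	1.53	110.4	fixed	-122.5
THR	OG1	N	CA	CB	1.43	109.6	chi1	0
THR	CG2	N	CA	CB	1.52	110.5	chi1	-122
VAL	CB	C	N	CA	1.53	110.4	fixed	-122.5
VAL	CG1	N	CA	CB	1.52	110.5	chi1	0
VAL	CG2	N	CA	CB	1.52	110.5	chi1	122
LEU	CB	C	N	CA	1.53	110.4	fixed	-122.5
LEU	CG	N	CA	CB	1.53	116.3	chi1	0
LEU	CD1	CA	CB	CG	1.52	110.7	chi2	0
LEU	CD2	CA	CB	CG	1.52	110.7	chi2	122
ILE	CB	C	N	CA	1.53	110.4	fixed	-122.5
ILE	CG1	N	CA	CB	1.53	110.4	chi1	0
ILE	CG2	N	CA	CB	1.52	110.5	chi1	-122
ILE	CD1	CA	CB	CG1	1.52	113.9	chi2	0
MET	CB	C	N	CA	1.53	110.4	fixed	-122.5
MET	CG	N	CA	CB	1.52	114.1	chi1	0
MET	SD	CA	CB	CG	1.81	112.7	chi2	0
MET	CE	CB	CG	SD	1.79	100.9	chi3	0
PHE	CB	C	N	CA	1.53	110.4	fixed	-122.5
PHE	CG	N	CA	CB	1.50	113.8	chi1	0
PHE	CD1	CA	CB	CG	1.39	120.8	chi2	0
PHE	CD2	CA	CB	CG	1.39	120.8	chi2	180
PHE	CE1	CB	CG	CD1	1.39	121.0	fixed	180
PHE	CE2	CB	CG	CD2	1.39	121.0	fixed	180
PHE	CZ	CG	CD1	CE1	1.39	120.0	fixed	0
TYR	CB	C	N	CA	1.53	110.4	fixed	-122.5
TYR	CG	N	CA	CB	1.50	113.8	chi1	0
TYR	CD1	CA	CB	CG	1.39	120.8	chi2	0
TYR	CD2	CA	CB	CG	1.39	120.8	chi2	180
TYR	CE1	CB	CG	CD1	1.39	121.0	fixed	180
TYR	CE2	CB	CG	CD2	1.39	121.0	fixed	180
TYR	CZ	CG	CD1	CE1	1.39	120.0	fixed	0
TYR	OH	CD1	CE1	CZ	1.38	119.9	fixed	180
TRP	CB	C	N	CA	1.53	110.4	fixed	-122.5
TRP	CG	N	CA	CB	1.50	113.6	chi1	0
TRP	CD1	CA	CB	CG	1.37	126.9	chi2	0
TRP	CD2	CA	CB	CG	1.43	126.7	chi2	180
TRP	NE1	CB	CG	CD1	1.38	110.2	fixed	180
TRP	CE2	CG	CD1	NE1	1.37	109.0	fixed	0
TRP	CE3	CD1	CG	CD2	1.40	133.9	fixed	180
TRP	CZ2	CG	CD2	CE2	1.40	122.4	fixed	180
TRP	CZ3	CE2	CD2	CE3	1.39	118.6	fixed	180
TRP	CH2	CD2	CE3	CZ3	1.37	121.1	fixed	0
HIS	CB	C	N	CA	1.53	110.4	fixed	-122.5
HIS	CG	N	CA	CB	1.50	113.8	chi1	0
HIS	ND1	CA	CB	CG	1.38	122.7	chi2	0
HIS	CD2	CA	CB	CG	1.36	131.1	chi2	180
HIS	CE1	CB	CG	ND1	1.32	109.0	fixed	180
HIS	NE2	CG	ND1	CE1	1.32	108.5	fixed	0
HID	CB	C	N	CA	1.53	110.4	fixed	-122.5
HID	CG	N	CA	CB	1.50	113.8	chi1	0
HID	ND1	CA	CB	CG	1.38	122.7	chi2	0
HID	CD2	CA	CB	CG	1.36	131.1	chi2	180
HID	CE1	CB	CG	ND1	1.32	109.0	fixed	180
HID	NE2	CG	ND1	CE1	1.32	108.5	fixed	0
HIE	CB	C	N	CA	1.53	110.4	fixed	-122.5
HIE	CG	N	CA	CB	1.50	113.8	chi1	0
HIE	ND1	CA	CB	CG	1.38	122.7	chi2	0
HIE	CD2	CA	CB	CG	1.36	131.1	chi2	180
HIE	CE1	CB	CG	ND1	1.32	109.0	fixed	180
HIE	NE2	CG	ND1	CE1	1.32	108.5	fixed	0
HIP	CB	C	N	CA	1.53	110.4	fixed	-122.5
HIP	CG	N	CA	CB	1.50	113.8	chi1	0
HIP	ND1	CA	CB	CG	1.38	122.7	chi2	0
HIP	CD2	CA	CB	CG	1.36	131.1	chi2	180
HIP	CE1	CB	CG	ND1	1.32	109.0	fixed	180
HIP	NE2	CG	ND1	CE1	1.32	108.5	fixed	0
ASP	CB	C	N	CA	1.53	110.4	fixed	-122.5
ASP	CG	N	CA	CB	1.52	113.0	chi1	0
ASP	OD1	CA	CB	CG	1.25	118.3	chi2	0
ASP	OD2	CA	CB	CG	1.25	118.3	chi2	180
ASN	CB	C	N	CA	1.53	110.4	fixed	-122.5
ASN	CG	N	CA	CB	1.52	112.7	chi1	0
ASN	OD1	CA	CB	CG	1.23	120.8	chi2	0
ASN	ND2	CA	CB	CG	1.33	116.5	chi2	180
GLU	CB	C	N	CA	1.53	110.4	fixed	-122.5
GLU	CG	N	CA	CB	1.52	113.8	chi1	0
GLU	CD	CA	CB	CG	1.52	112.6	chi2	0
GLU	OE1	CB	CG	CD	1.25	118.3	chi3	0
GLU	OE2	CB	CG	CD	1.25	118.3	chi3	180
GLN	CB	C	N	CA	1.53	110.4	fixed	-122.5
GLN	CG	N	CA	CB	1.52	113.8	chi1	0
GLN	CD	CA	CB	CG	1.52	112.6	chi2	0
GLN	OE1	CB	CG	CD	1.23	120.8	chi3	0
GLN	NE2	CB	CG	CD	1.33	116.5	chi3	180
LYS	CB	C	N	CA	1.53	110.4	fixed	-122.5
LYS	CG	N	CA	CB	1.52	113.8	chi1	0
LYS	CD	CA	CB	CG	1.52	111.3	chi2	0
LYS	CE	CB	CG	CD	1.52	111.3	chi3	0
LYS	NZ	CG	CD	CE	1.49	111.9	chi4	0
ARG	CB	C	N	CA	1.53	110.4	fixed	-122.5
ARG	CG	N	CA	CB	1.52	113.8	chi1	0
ARG	CD	CA	CB	CG	1.52	111.3	chi2	0
ARG	NE	CB	CG	CD	1.46	112.0	chi3	0
ARG	CZ	CG	CD	NE	1.33	124.2	chi4	0
ARG	NH1	CD	NE	CZ	1.33	120.0	fixed	0
ARG	NH2	CD	NE	CZ	1.33	120.0	fixed	180
PRO	CB	C	N	CA	1.53	103.2	fixed	-120
PRO	CG	N	CA	CB	1.49	104.5	chi1	0
PRO	CD	CA	CB	CG	1.50	105.5	chi2	0
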