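# Simplified united-atom parameter set, heavy atoms only.
# restype "*" rows match the named backbone atom in any amino-acid residue.
# charge: elementary charge units; rmin: vdW minimum-distance radius (A);
# eps: vdW well depth (kcal/mol).
restype	atom	charge	rmin	eps
*	N	-0.40	1.85	0.12
*	CA	0.15	2.00	0.10
*	C	0.55	1.95	0.08
*	O	-0.55	1.72	0.15
*	OXT	-0.55	1.72	0.15
GLY	CA	0.40	2.00	0.10
ALA	CB	0.25	2.00	0.10
SER	CB	0.65	2.00	0.10
SER	OG	-0.40	1.72	0.15
CYS	CB	0.45	2.00	0.10
CYS	SG	-0.20	2.00	0.20
THR	CB	0.50	2.00	0.10
THR	OG1	-0.40	1.72	0.15
THR	CG2	0.15	2.00	0.10
VAL	CB	0.05	2.00	0.10
VAL	CG1	0.10	2.00	0.10
VAL	CG2	0.10	2.00	0.10
LEU	CB	0.05	2.00	0.10
LEU	CG	0.00	2.00	0.10
LEU	CD1	0.10	2.00	0.10
LEU	CD2	0.10	2.00	0.10
ILE	CB	0.05	2.00	0.10
ILE	CG1	0.00	2.00	0.10
ILE	CG2	0.10	2.00	0.10
ILE	CD1	0.10	2.00	0.10
MET	CB	0.15	2.00	0.10
MET	CG	0.20	2.00	0.10
MET	SD	-0.30	2.00	0.20
MET	CE	0.20	2.00	0.10
PHE	CB	0.25	2.00	0.10
PHE	CG	0.00	1.95	0.08
PHE	CD1	0.00	1.95	0.08
PHE	CD2	0.00	1.95	0.08
PHE	CE1	0.00	1.95	0.08
PHE	CE2	0.00	1.95	0.08
PHE	CZ	0.00	1.95	0.08
TYR	CB	0.25	2.00	0.10
TYR	CG	0.00	1.95	0.08
TYR	CD1	0.00	1.95	0.08
TYR	CD2	0.00	1.95	0.08
TYR	CE1	0.10	1.95	0.08
TYR	CE2	0.10	1.95	0.08
TYR	CZ	0.30	1.95	0.08
TYR	OH	-0.50	1.72	0.15
TRP	CB	0.25	2.00	0.10
TRP	CG	0.00	1.95	0.08
TRP	CD1	0.10	1.95	0.08
TRP	CD2	0.00	1.95	0.08
TRP	NE1	-0.30	1.85	0.12
TRP	CE2	0.20	1.95	0.08
TRP	CE3	0.00	1.95	0.08
TRP	CZ2	0.00	1.95	0.08
TRP	CZ3	0.00	1.95	0.08
TRP	CH2	0.00	1.95	0.08
ASP	CB	0.05	2.00	0.10
ASP	CG	0.50	1.95	0.08
ASP	OD1	-0.65	1.72	0.15
ASP	OD2	-0.65	1.72	0.15
GLU	CB	0.05	2.00	0.10
GLU	CG	0.10	2.00	0.10
GLU	CD	0.50	1.95	0.08
GLU	OE1	-0.70	1.72	0.15
GLU	OE2	-0.70	1.72	0.15
ASN	CB	0.15	2.00	0.10
ASN	CG	0.55	1.95	0.08
ASN	OD1	-0.55	1.72	0.15
ASN	ND2	0.10	1.85	0.12
GLN	CB	0.15	2.00	0.10
GLN	CG	0.00	2.00	0.10
GLN	CD	0.55	1.95	0.08
GLN	OE1	-0.55	1.72	0.15
GLN	NE2	0.10	1.85	0.12
LYS	CB	0.05	2.00	0.10
LYS	CG	0.00	2.00	0.10
LYS	CD	0.10	2.00	0.10
LYS	CE	0.25	2.00	0.10
LYS	NZ	0.85	1.85	0.12
ARG	CB	0.05	2.00	0.10
ARG	CG	0.00	2.00	0.10
ARG	CD	0.10	2.00	0.10
ARG	NE	-0.30	1.85	0.12
ARG	CZ	0.80	1.95	0.08
ARG	NH1	0.30	1.85	0.12
ARG	NH2	0.30	1.85	0.12
PRO	CB	0.15	2.00	0.10
PRO	CG	0.10	2.00	0.10
PRO	CD	0.00	2.00	0.10
HID	CB	0.15	2.00	0.10
HID	CG	0.10	1.95	0.08
HID	ND1	-0.30	1.85	0.12
HID	CD2	0.10	1.95	0.08
HID	CE1	0.30	1.95	0.08
HID	NE2	-0.10	1.85	0.12
HIE	CB	0.15	2.00	0.10
HIE	CG	0.10	1.95	0.08
HIE	ND1	-0.10	1.85	0.12
HIE	CD2	0.10	1.95	0.08
HIE	CE1	0.30	1.95	0.08
HIE	NE2	-0.30	1.85	0.12
HIP	CB	0.15	2.00	0.10
HIP	CG	0.10	1.95	0.08
HIP	ND1	0.20	1.85	0.12
HIP	CD2	0.20	1.95	0.08
HIP	CE1	0.40	1.95	0.08
HIP	NE2	0.20	1.85	0.12
HIS	CB	0.15	2.00	0.10
HIS	CG	0.10	1.95	0.08
HIS	ND1	-0.10	1.85	0.12
HIS	CD2	0.10	1.95	0.08
HIS	CE1	0.30	1.95	0.08
HIS	NE2	-0.30	1.85	0.12
DA	P	1.20	2.10	0.20
DA	OP1	-0.80	1.72	0.15
DA	OP2	-0.80	1.72	0.15
DA	O5'	-0.40	1.72	0.15
DA	C5'	0.10	2.00	0.10
DA	C4'	0.10	2.00	0.10
DA	O4'	-0.30	1.72	0.15
DA	C3'	0.10	2.00	0.10
DA	O3'	-0.40	1.72	0.15
DA	C2'	0.10	2.00	0.10
DA	C1'	0.20	2.00	0.10
DA	N9	-0.20	1.85	0.12
DA	C8	0.20	1.95	0.08
DA	N7	-0.30	1.85	0.12
DA	C5	0.00	1.95	0.08
DA	C6	0.30	1.95	0.08
DA	N6	-0.40	1.85	0.12
DA	N1	-0.30	1.85	0.12
DA	C2	0.30	1.95	0.08
DA	N3	-0.30	1.85	0.12
DA	C4	0.30	1.95	0.08
DT	P	1.20	2.10	0.20
DT	OP1	-0.80	1.72	0.15
DT	OP2	-0.80	1.72	0.15
DT	O5'	-0.40	1.72	0.15
DT	C5'	0.10	2.00	0.10
DT	C4'	0.10	2.00	0.10
DT	O4'	-0.30	1.72	0.15
DT	C3'	0.10	2.00	0.10
DT	O3'	-0.40	1.72	0.15
DT	C2'	0.10	2.00	0.10
DT	C1'	0.20	2.00	0.10
DT	N1	-0.20	1.85	0.12
DT	C2	0.40	1.95	0.08
DT	O2	-0.45	1.72	0.15
DT	N3	-0.30	1.85	0.12
DT	C4	0.40	1.95	0.08
DT	O4	-0.45	1.72	0.15
DT	C5	0.00	1.95	0.08
DT	C7	0.10	2.00	0.10
DT	C6	0.10	1.95	0.08
DG	P	1.20	2.10	0.20
DG	OP1	-0.80	1.72	0.15
DG	OP2	-0.80	1.72	0.15
DG	O5'	-0.40	1.72	0.15
DG	C5'	0.10	2.00	0.10
DG	C4'	0.10	2.00	0.10
DG	O4'	-0.30	1.72	0.15
DG	C3'	0.10	2.00	0.10
DG	O3'	-0.40	1.72	0.15
DG	C2'	0.10	2.00	0.10
DG	C1'	0.20	2.00	0.10
DG	N9	-0.20	1.85	0.12
DG	C8	0.20	1.95	0.08
DG	N7	-0.30	1.85	0.12
DG	C5	0.00	1.95	0.08
DG	C6	0.40	1.95	0.08
DG	O6	-0.45	1.72	0.15
DG	N1	-0.30	1.85	0.12
DG	C2	0.40	1.95	0.08
DG	N2	-0.40	1.85	0.12
DG	N3	-0.30	1.85	0.12
DG	C4	0.30	1.95	0.08
DC	P	1.20	2.10	0.20
DC	OP1	-0.80	1.72	0.15
DC	OP2	-0.80	1.72	0.15
DC	O5'	-0.40	1.72	0.15
DC	C5'	0.10	2.00	0.10
DC	C4'	0.10	2.00	0.10
DC	O4'	-0.30	1.72	0.15
DC	C3'	0.10	2.00	0.10
DC	O3'	-0.40	1.72	0.15
DC	C2'	0.10	2.00	0.10
DC	C1'	0.20	2.00	0.10
DC	N1	-0.20	1.85	0.12
DC	C2	0.40	1.95	0.08
DC	O2	-0.45	1.72	0.15
DC	N3	-0.30	1.85	0.12
DC	C4	0.30	1.95	0.08
DC	N4	-0.40	1.85	0.12
DC	C5	0.00	1.95	0.08
DC	C6	0.10	1.95	0.08
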