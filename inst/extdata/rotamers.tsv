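# Compact backbone-independent rotamer library (chi angles, degrees).
# Modal chi values; kept deliberately small so conformation spaces stay
# exactly enumerable. GLY and ALA carry a single trivial rotamer.
restype	rot	chi1	chi2	chi3	chi4
GLY	1	NA	NA	NA	NA
ALA	1	NA	NA	NA	NA
SER	1	-65	NA	NA	NA
SER	2	178	NA	NA	NA
SER	3	64	NA	NA	NA
CYS	1	-65	NA	NA	NA
CYS	2	180	NA	NA	NA
CYS	3	63	NA	NA	NA
THR	1	-60	NA	NA	NA
THR	2	180	NA	NA	NA
THR	3	60	NA	NA	NA
VAL	1	175	NA	NA	NA
VAL	2	-60	NA	NA	NA
VAL	3	63	NA	NA	NA
LEU	1	-65	175	NA	NA
LEU	2	177	65	NA	NA
ILE	1	-65	170	NA	NA
ILE	2	180	170	NA	NA
MET	1	-65	-65	-70	NA
MET	2	180	180	180	NA
PHE	1	-65	90	NA	NA
PHE	2	180	80	NA	NA
TYR	1	-65	90	NA	NA
TYR	2	180	80	NA	NA
TRP	1	-65	95	NA	NA
TRP	2	180	-105	NA	NA
HIS	1	-65	-70	NA	NA
HIS	2	177	75	NA	NA
HID	1	-65	-70	NA	NA
HID	2	177	75	NA	NA
HIE	1	-65	-70	NA	NA
HIE	2	177	75	NA	NA
HIP	1	-65	-70	NA	NA
HIP	2	177	75	NA	NA
ASP	1	-70	-20	NA	NA
ASP	2	180	15	NA	NA
ASN	1	-65	-20	NA	NA
ASN	2	180	30	NA	NA
GLU	1	-65	180	-10	NA
GLU	2	180	180	10	NA
GLN	1	-65	180	-25	NA
GLN	2	180	180	30	NA
LYS	1	-65	180	180	180
LYS	2	180	180	180	180
ARG	1	-65	180	180	90
ARG	2	180	180	180	90
PRO	1	-26	38	NA	NA
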