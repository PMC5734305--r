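# per-atom soft-core scoring parameters v1: vdW radius (A), hydrophobic flag, formal charge (e)
res_name	atom	element	radius	hydrophobic	charge
ALA	N	N	1.75	0	0.0
ALA	CA	C	2.0	0	0.0
ALA	C	C	2.0	0	0.0
ALA	O	O	1.7	0	0.0
ALA	CB	C	2.0	1	0.0
ARG	N	N	1.75	0	0.0
ARG	CA	C	2.0	0	0.0
ARG	C	C	2.0	0	0.0
ARG	O	O	1.7	0	0.0
ARG	CB	C	2.0	1	0.0
ARG	CG	C	2.0	1	0.0
ARG	CD	C	2.0	1	0.0
ARG	NE	N	1.75	0	0.0
ARG	CZ	C	2.0	1	1.0
ARG	NH1	N	1.75	0	0.0
ARG	NH2	N	1.75	0	0.0
ASN	N	N	1.75	0	0.0
ASN	CA	C	2.0	0	0.0
ASN	C	C	2.0	0	0.0
ASN	O	O	1.7	0	0.0
ASN	CB	C	2.0	1	0.0
ASN	CG	C	2.0	1	0.0
ASN	OD1	O	1.7	0	0.0
ASN	ND2	N	1.75	0	0.0
ASP	N	N	1.75	0	0.0
ASP	CA	C	2.0	0	0.0
ASP	C	C	2.0	0	0.0
ASP	O	O	1.7	0	0.0
ASP	CB	C	2.0	1	0.0
ASP	CG	C	2.0	1	-1.0
ASP	OD1	O	1.7	0	0.0
ASP	OD2	O	1.7	0	0.0
CYS	N	N	1.75	0	0.0
CYS	CA	C	2.0	0	0.0
CYS	C	C	2.0	0	0.0
CYS	O	O	1.7	0	0.0
CYS	CB	C	2.0	1	0.0
CYS	SG	S	2.05	0	0.0
GLN	N	N	1.75	0	0.0
GLN	CA	C	2.0	0	0.0
GLN	C	C	2.0	0	0.0
GLN	O	O	1.7	0	0.0
GLN	CB	C	2.0	1	0.0
GLN	CG	C	2.0	1	0.0
GLN	CD	C	2.0	1	0.0
GLN	OE1	O	1.7	0	0.0
GLN	NE2	N	1.75	0	0.0
GLU	N	N	1.75	0	0.0
GLU	CA	C	2.0	0	0.0
GLU	C	C	2.0	0	0.0
GLU	O	O	1.7	0	0.0
GLU	CB	C	2.0	1	0.0
GLU	CG	C	2.0	1	0.0
GLU	CD	C	2.0	1	-1.0
GLU	OE1	O	1.7	0	0.0
GLU	OE2	O	1.7	0	0.0
GLY	N	N	1.75	0	0.0
GLY	CA	C	2.0	0	0.0
GLY	C	C	2.0	0	0.0
GLY	O	O	1.7	0	0.0
HIS	N	N	1.75	0	0.0
HIS	CA	C	2.0	0	0.0
HIS	C	C	2.0	0	0.0
HIS	O	O	1.7	0	0.0
HIS	CB	C	2.0	1	0.0
HIS	CG	C	2.0	1	0.0
HIS	ND1	N	1.75	0	0.0
HIS	CD2	C	2.0	1	0.0
HIS	CE1	C	2.0	1	0.0
HIS	NE2	N	1.75	0	0.0
ILE	N	N	1.75	0	0.0
ILE	CA	C	2.0	0	0.0
ILE	C	C	2.0	0	0.0
ILE	O	O	1.7	0	0.0
ILE	CB	C	2.0	1	0.0
ILE	CG1	C	2.0	1	0.0
ILE	CG2	C	2.0	1	0.0
ILE	CD1	C	2.0	1	0.0
LEU	N	N	1.75	0	0.0
LEU	CA	C	2.0	0	0.0
LEU	C	C	2.0	0	0.0
LEU	O	O	1.7	0	0.0
LEU	CB	C	2.0	1	0.0
LEU	CG	C	2.0	1	0.0
LEU	CD1	C	2.0	1	0.0
LEU	CD2	C	2.0	1	0.0
LYS	N	N	1.75	0	0.0
LYS	CA	C	2.0	0	0.0
LYS	C	C	2.0	0	0.0
LYS	O	O	1.7	0	0.0
LYS	CB	C	2.0	1	0.0
LYS	CG	C	2.0	1	0.0
LYS	CD	C	2.0	1	0.0
LYS	CE	C	2.0	1	0.0
LYS	NZ	N	1.75	0	1.0
MET	N	N	1.75	0	0.0
MET	CA	C	2.0	0	0.0
MET	C	C	2.0	0	0.0
MET	O	O	1.7	0	0.0
MET	CB	C	2.0	1	0.0
MET	CG	C	2.0	1	0.0
MET	SD	S	2.05	0	0.0
MET	CE	C	2.0	1	0.0
PHE	N	N	1.75	0	0.0
PHE	CA	C	2.0	0	0.0
PHE	C	C	2.0	0	0.0
PHE	O	O	1.7	0	0.0
PHE	CB	C	2.0	1	0.0
PHE	CG	C	2.0	1	0.0
PHE	CD1	C	2.0	1	0.0
PHE	CD2	C	2.0	1	0.0
PHE	CE1	C	2.0	1	0.0
PHE	CE2	C	2.0	1	0.0
PHE	CZ	C	2.0	1	0.0
PRO	N	N	1.75	0	0.0
PRO	CA	C	2.0	0	0.0
PRO	C	C	2.0	0	0.0
PRO	O	O	1.7	0	0.0
PRO	CB	C	2.0	1	0.0
PRO	CG	C	2.0	1	0.0
PRO	CD	C	2.0	1	0.0
SER	N	N	1.75	0	0.0
SER	CA	C	2.0	0	0.0
SER	C	C	2.0	0	0.0
SER	O	O	1.7	0	0.0
SER	CB	C	2.0	1	0.0
SER	OG	O	1.7	0	0.0
THR	N	N	1.75	0	0.0
THR	CA	C	2.0	0	0.0
THR	C	C	2.0	0	0.0
THR	O	O	1.7	0	0.0
THR	CB	C	2.0	1	0.0
THR	OG1	O	1.7	0	0.0
THR	CG2	C	2.0	1	0.0
TRP	N	N	1.75	0	0.0
TRP	CA	C	2.0	0	0.0
TRP	C	C	2.0	0	0.0
TRP	O	O	1.7	0	0.0
TRP	CB	C	2.0	1	0.0
TRP	CG	C	2.0	1	0.0
TRP	CD1	C	2.0	1	0.0
TRP	CD2	C	2.0	1	0.0
TRP	NE1	N	1.75	0	0.0
TRP	CE2	C	2.0	1	0.0
TRP	CE3	C	2.0	1	0.0
TRP	CZ2	C	2.0	1	0.0
TRP	CZ3	C	2.0	1	0.0
TRP	CH2	C	2.0	1	0.0
TYR	N	N	1.75	0	0.0
TYR	CA	C	2.0	0	0.0
TYR	C	C	2.0	0	0.0
TYR	O	O	1.7	0	0.0
TYR	CB	C	2.0	1	0.0
TYR	CG	C	2.0	1	0.0
TYR	CD1	C	2.0	1	0.0
TYR	CD2	C	2.0	1	0.0
TYR	CE1	C	2.0	1	0.0
TYR	CE2	C	2.0	1	0.0
TYR	CZ	C	2.0	1	0.0
TYR	OH	O	1.7	0	0.0
VAL	N	N	1.75	0	0.0
VAL	CA	C	2.0	0	0.0
VAL	C	C	2.0	0	0.0
VAL	O	O	1.7	0	0.0
VAL	CB	C	2.0	1	0.0
VAL	CG1	C	2.0	1	0.0
VAL	CG2	C	2.0	1	0.0
HYP	N	N	1.75	0	0.0
HYP	CA	C	2.0	0	0.0
HYP	C	C	2.0	0	0.0
HYP	O	O	1.7	0	0.0
HYP	CB	C	2.0	1	0.0
HYP	CG	C	2.0	1	0.0
HYP	CD	C	2.0	1	0.0
HYP	OD1	O	1.7	0	0.0
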