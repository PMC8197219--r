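resid	atom	code
ALA	N	NCP
ALA	CA	C3P
ALA	C	CCP
ALA	O	OCP
ALA	OXT	OCC
ALA	CB	C3N
ARG	N	NCP
ARG	CA	C3P
ARG	C	CCP
ARG	O	OCP
ARG	OXT	OCC
ARG	CB	C3N
ARG	CG	C3N
ARG	CD	C3N
ARG	NE	NCC
ARG	CZ	CCP
ARG	NH1	NCC
ARG	NH2	NCC
ASN	N	NCP
ASN	CA	C3P
ASN	C	CCP
ASN	O	OCP
ASN	OXT	OCC
ASN	CB	C3N
ASN	CG	CCP
ASN	OD1	OCP
ASN	ND2	NCP
ASP	N	NCP
ASP	CA	C3P
ASP	C	CCP
ASP	O	OCP
ASP	OXT	OCC
ASP	CB	C3N
ASP	CG	CCP
ASP	OD1	OCC
ASP	OD2	OCC
CYS	N	NCP
CYS	CA	C3P
CYS	C	CCP
CYS	O	OCP
CYS	OXT	OCC
CYS	CB	C3N
CYS	SG	S3N
GLN	N	NCP
GLN	CA	C3P
GLN	C	CCP
GLN	O	OCP
GLN	OXT	OCC
GLN	CB	C3N
GLN	CG	C3N
GLN	CD	CCP
GLN	OE1	OCP
GLN	NE2	NCP
GLU	N	NCP
GLU	CA	C3P
GLU	C	CCP
GLU	O	OCP
GLU	OXT	OCC
GLU	CB	C3N
GLU	CG	C3N
GLU	CD	CCP
GLU	OE1	OCC
GLU	OE2	OCC
GLY	N	NCP
GLY	CA	C3P
GLY	C	CCP
GLY	O	OCP
GLY	OXT	OCC
HIS	N	NCP
HIS	CA	C3P
HIS	C	CCP
HIS	O	OCP
HIS	OXT	OCC
HIS	CB	C3N
HIS	CG	CRP
HIS	ND1	NRV
HIS	CD2	CRP
HIS	CE1	CRP
HIS	NE2	NRV
ILE	N	NCP
ILE	CA	C3P
ILE	C	CCP
ILE	O	OCP
ILE	OXT	OCC
ILE	CB	C3N
ILE	CG1	C3N
ILE	CG2	C3N
ILE	CD1	C3N
LEU	N	NCP
LEU	CA	C3P
LEU	C	CCP
LEU	O	OCP
LEU	OXT	OCC
LEU	CB	C3N
LEU	CG	C3N
LEU	CD1	C3N
LEU	CD2	C3N
LYS	N	NCP
LYS	CA	C3P
LYS	C	CCP
LYS	O	OCP
LYS	OXT	OCC
LYS	CB	C3N
LYS	CG	C3N
LYS	CD	C3N
LYS	CE	C3N
LYS	NZ	N3C
MET	N	NCP
MET	CA	C3P
MET	C	CCP
MET	O	OCP
MET	OXT	OCC
MET	CB	C3N
MET	CG	C3N
MET	SD	S3N
MET	CE	C3N
PHE	N	NCP
PHE	CA	C3P
PHE	C	CCP
PHE	O	OCP
PHE	OXT	OCC
PHE	CB	C3N
PHE	CG	CRN
PHE	CD1	CRN
PHE	CD2	CRN
PHE	CE1	CRN
PHE	CE2	CRN
PHE	CZ	CRN
PRO	N	NCP
PRO	CA	C3P
PRO	C	CCP
PRO	O	OCP
PRO	OXT	OCC
PRO	CB	C3N
PRO	CG	C3N
PRO	CD	C3N
SER	N	NCP
SER	CA	C3P
SER	C	CCP
SER	O	OCP
SER	OXT	OCC
SER	CB	C3N
SER	OG	O3P
THR	N	NCP
THR	CA	C3P
THR	C	CCP
THR	O	OCP
THR	OXT	OCC
THR	CB	C3N
THR	OG1	O3P
THR	CG2	C3N
TRP	N	NCP
TRP	CA	C3P
TRP	C	CCP
TRP	O	OCP
TRP	OXT	OCC
TRP	CB	C3N
TRP	CG	CRN
TRP	CD1	CRP
TRP	CD2	CRN
TRP	NE1	NRV
TRP	CE2	CRP
TRP	CE3	CRN
TRP	CZ2	CRN
TRP	CZ3	CRN
TRP	CH2	CRN
TYR	N	NCP
TYR	CA	C3P
TYR	C	CCP
TYR	O	OCP
TYR	OXT	OCC
TYR	CB	C3N
TYR	CG	CRN
TYR	CD1	CRN
TYR	CD2	CRN
TYR	CE1	CRN
TYR	CE2	CRN
TYR	CZ	CRP
TYR	OH	O3P
VAL	N	NCP
VAL	CA	C3P
VAL	C	CCP
VAL	O	OCP
VAL	OXT	OCC
VAL	CB	C3N
VAL	CG1	C3N
VAL	CG2	C3N
ZN	ZN	MET
MG	MG	MET
CA	CA	MET
FE	FE	MET
MN	MN	MET
NA	NA	MET
K	K	MET
CU	CU	MET
NI	NI	MET
CO	CO	MET
CD	CD	MET
PO4	P	PHO
PO4	O1	OCC
PO4	O2	OCC
PO4	O3	OCC
PO4	O4	OCC
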