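# Physicochemical atom classes for the 20 standard amino acids.
# res "*" rows are backbone atoms shared by every residue type; a
# residue-specific row overrides the wildcard for the same atom name.
# classes: comma-separated subset of
#   aromatic,acceptor,donor,hydrophobic,positive,negative
res	atom	classes
*	N	donor
*	CA	hydrophobic
*	C
*	O	acceptor
*	OXT	acceptor
ALA	CB	hydrophobic
ARG	CB	hydrophobic
ARG	CG	hydrophobic
ARG	CD	hydrophobic
ARG	NE	donor,positive
ARG	CZ
ARG	NH1	donor,positive
ARG	NH2	donor,positive
ASN	CB	hydrophobic
ASN	CG
ASN	OD1	acceptor
ASN	ND2	donor
ASP	CB	hydrophobic
ASP	CG
ASP	OD1	acceptor,negative
ASP	OD2	acceptor,negative
CYS	CB	hydrophobic
CYS	SG	hydrophobic,donor
GLN	CB	hydrophobic
GLN	CG	hydrophobic
GLN	CD
GLN	OE1	acceptor
GLN	NE2	donor
GLU	CB	hydrophobic
GLU	CG	hydrophobic
GLU	CD
GLU	OE1	acceptor,negative
GLU	OE2	acceptor,negative
HIS	CB	hydrophobic
HIS	CG	aromatic
HIS	ND1	aromatic,donor,acceptor
HIS	CD2	aromatic
HIS	CE1	aromatic
HIS	NE2	aromatic,donor,acceptor
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
LYS	CE	hydrophobic
LYS	NZ	donor,positive
MET	CB	hydrophobic
MET	CG	hydrophobic
MET	SD	hydrophobic
MET	CE	hydrophobic
PHE	CB	hydrophobic
PHE	CG	aromatic,hydrophobic
PHE	CD1	aromatic,hydrophobic
PHE	CD2	aromatic,hydrophobic
PHE	CE1	aromatic,hydrophobic
PHE	CE2	aromatic,hydrophobic
PHE	CZ	aromatic,hydrophobic
PRO	CB	hydrophobic
PRO	CG	hydrophobic
PRO	CD	hydrophobic
SER	CB	hydrophobic
SER	OG	donor,acceptor
THR	CB	hydrophobic
THR	OG1	donor,acceptor
THR	CG2	hydrophobic
TRP	CB	hydrophobic
TRP	CG	aromatic,hydrophobic
TRP	CD1	aromatic,hydrophobic
TRP	CD2	aromatic,hydrophobic
TRP	NE1	aromatic,donor
TRP	CE2	aromatic,hydrophobic
TRP	CE3	aromatic,hydrophobic
TRP	CZ2	aromatic,hydrophobic
TRP	CZ3	aromatic,hydrophobic
TRP	CH2	aromatic,hydrophobic
TYR	CB	hydrophobic
TYR	CG	aromatic,hydrophobic
TYR	CD1	aromatic,hydrophobic
TYR	CD2	aromatic,hydrophobic
TYR	CE1	aromatic,hydrophobic
TYR	CE2	aromatic,hydrophobic
TYR	CZ	aromatic,hydrophobic
TYR	OH	donor,acceptor
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
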