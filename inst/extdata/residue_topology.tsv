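residue	atoms	bonds
ALA	N CA C O CB	N-CA CA-C C-O CA-CB
ARG	N CA C O CB CG CD NE CZ NH1 NH2	N-CA CA-C C-O CA-CB CB-CG CG-CD CD-NE NE-CZ CZ-NH1 CZ-NH2
ASN	N CA C O CB CG OD1 ND2	N-CA CA-C C-O CA-CB CB-CG CG-OD1 CG-ND2
ASP	N CA C O CB CG OD1 OD2	N-CA CA-C C-O CA-CB CB-CG CG-OD1 CG-OD2
CYS	N CA C O CB SG	N-CA CA-C C-O CA-CB CB-SG
GLN	N CA C O CB CG CD OE1 NE2	N-CA CA-C C-O CA-CB CB-CG CG-CD CD-OE1 CD-NE2
GLU	N CA C O CB CG CD OE1 OE2	N-CA CA-C C-O CA-CB CB-CG CG-CD CD-OE1 CD-OE2
GLY	N CA C O	N-CA CA-C C-O
HIS	N CA C O CB CG ND1 CD2 CE1 NE2	N-CA CA-C C-O CA-CB CB-CG CG-ND1 CG-CD2 ND1-CE1 CD2-NE2 CE1-NE2
ILE	N CA C O CB CG1 CG2 CD1	N-CA CA-C C-O CA-CB CB-CG1 CB-CG2 CG1-CD1
LEU	N CA C O CB CG CD1 CD2	N-CA CA-C C-O CA-CB CB-CG CG-CD1 CG-CD2
LYS	N CA C O CB CG CD CE NZ	N-CA CA-C C-O CA-CB CB-CG CG-CD CD-CE CE-NZ
MET	N CA C O CB CG SD CE	N-CA CA-C C-O CA-CB CB-CG CG-SD SD-CE
PHE	N CA C O CB CG CD1 CD2 CE1 CE2 CZ	N-CA CA-C C-O CA-CB CB-CG CG-CD1 CG-CD2 CD1-CE1 CD2-CE2 CE1-CZ CE2-CZ
PRO	N CA C O CB CG CD	N-CA CA-C C-O CA-CB CB-CG CG-CD CD-N
SER	N CA C O CB OG	N-CA CA-C C-O CA-CB CB-OG
THR	N CA C O CB OG1 CG2	N-CA CA-C C-O CA-CB CB-OG1 CB-CG2
TRP	N CA C O CB CG CD1 CD2 NE1 CE2 CE3 CZ2 CZ3 CH2	N-CA CA-C C-O CA-CB CB-CG CG-CD1 CG-CD2 CD1-NE1 NE1-CE2 CD2-CE2 CD2-CE3 CE2-CZ2 CE3-CZ3 CZ2-CH2 CZ3-CH2
TYR	N CA C O CB CG CD1 CD2 CE1 CE2 CZ OH	N-CA CA-C C-O CA-CB CB-CG CG-CD1 CG-CD2 CD1-CE1 CD2-CE2 CE1-CZ CE2-CZ CZ-OH
VAL	N CA C O CB CG1 CG2	N-CA CA-C C-O CA-CB CB-CG1 CB-CG2
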