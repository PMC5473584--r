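# Synthetic minimal component dictionary for mmtfr tests and the bundled
# residue vocabulary. Hand-written in Chemical Component Dictionary style;
# NOT the archival CCD. Heavy atoms only except where noted.
data_components_synthetic
#
loop_
_chem_comp.id
_chem_comp.type
_chem_comp.one_letter_code
GLY 'PEPTIDE LINKING'   G
ALA 'L-PEPTIDE LINKING' A
SER 'L-PEPTIDE LINKING' S
CYS 'L-PEPTIDE LINKING' C
U   'RNA LINKING'       U
HOH NON-POLYMER         ?
LG1 NON-POLYMER         ?
#
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
_chem_comp_atom.charge
GLY N   N 0
GLY CA  C 0
GLY C   C 0
GLY O   O 0
ALA N   N 0
ALA CA  C 0
ALA C   C 0
ALA O   O 0
ALA CB  C 0
SER N   N 0
SER CA  C 0
SER C   C 0
SER O   O 0
SER CB  C 0
SER OG  O 0
SER HA  H 0
SER HB2 H 0
SER HB3 H 0
SER HG  H 0
CYS N   N 0
CYS CA  C 0
CYS C   C 0
CYS O   O 0
CYS CB  C 0
CYS SG  S 0
U   P     P 0
U   OP1   O 0
U   OP2   O 0
U   "O5'" O 0
U   "C5'" C 0
U   "C4'" C 0
U   "O4'" O 0
U   "C3'" C 0
U   "O3'" O 0
U   "C2'" C 0
U   "O2'" O 0
U   "C1'" C 0
U   N1    N 0
U   C2    C 0
U   O2    O 0
U   N3    N 0
U   C4    C 0
U   O4    O 0
U   C5    C 0
U   C6    C 0
HOH O   O 0
LG1 C1  C 0
LG1 C2  C 0
LG1 C3  C 0
LG1 C4  C 0
LG1 C5  C 0
LG1 C6  C 0
LG1 N7  N 0
LG1 C8  C 0
LG1 O9  O 0
LG1 O10 O 0
LG1 C11 C 0
LG1 N12 N 1
#
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.value_order
GLY N   CA  SING
GLY CA  C   SING
GLY C   O   DOUB
ALA N   CA  SING
ALA CA  C   SING
ALA C   O   DOUB
ALA CA  CB  SING
SER N   CA  SING
SER CA  C   SING
SER C   O   DOUB
SER CA  CB  SING
SER CB  OG  SING
SER CA  HA  SING
SER CB  HB2 SING
SER CB  HB3 SING
SER OG  HG  SING
CYS N   CA  SING
CYS CA  C   SING
CYS C   O   DOUB
CYS CA  CB  SING
CYS CB  SG  SING
U   P     OP1   DOUB
U   P     OP2   SING
U   P     "O5'" SING
U   "O5'" "C5'" SING
U   "C5'" "C4'" SING
U   "C4'" "O4'" SING
U   "C4'" "C3'" SING
U   "C3'" "O3'" SING
U   "C3'" "C2'" SING
U   "C2'" "O2'" SING
U   "C2'" "C1'" SING
U   "C1'" "O4'" SING
U   "C1'" N1    SING
U   N1    C2    SING
U   C2    O2    DOUB
U   C2    N3    SING
U   N3    C4    SING
U   C4    O4    DOUB
U   C4    C5    SING
U   C5    C6    DOUB
U   C6    N1    SING
LG1 C1  C2  DOUB
LG1 C2  C3  SING
LG1 C3  C4  DOUB
LG1 C4  C5  SING
LG1 C5  C6  DOUB
LG1 C6  C1  SING
LG1 C3  N7  SING
LG1 N7  C8  SING
LG1 C8  O9  DOUB
LG1 C8  O10 SING
LG1 O10 C11 SING
LG1 C6  N12 SING
#
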