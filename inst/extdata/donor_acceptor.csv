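resid,atom,role
A,N6,donor
A,N1,acceptor
A,N3,acceptor
A,N7,acceptor
C,N4,donor
C,N3,acceptor
C,O2,acceptor
G,N1,donor
G,N2,donor
G,O6,acceptor
G,N3,acceptor
G,N7,acceptor
U,N3,donor
U,O2,acceptor
U,O4,acceptor
A,O2',donor
A,O2',acceptor
A,OP1,acceptor
A,OP2,acceptor
A,O3',acceptor
A,O4',acceptor
A,O5',acceptor
C,O2',donor
C,O2',acceptor
C,OP1,acceptor
C,OP2,acceptor
C,O3',acceptor
C,O4',acceptor
C,O5',acceptor
G,O2',donor
G,O2',acceptor
G,OP1,acceptor
G,OP2,acceptor
G,O3',acceptor
G,O4',acceptor
G,O5',acceptor
U,O2',donor
U,O2',acceptor
U,OP1,acceptor
U,OP2,acceptor
U,O3',acceptor
U,O4',acceptor
U,O5',acceptor
ALA,N,donor
ALA,O,acceptor
ARG,N,donor
ARG,O,acceptor
ARG,NE,donor
ARG,NH1,donor
ARG,NH2,donor
ASN,N,donor
ASN,O,acceptor
ASN,ND2,donor
ASN,OD1,acceptor
ASP,N,donor
ASP,O,acceptor
ASP,OD1,acceptor
ASP,OD2,acceptor
CYS,N,donor
CYS,O,acceptor
CYS,SG,donor
CYS,SG,acceptor
GLN,N,donor
GLN,O,acceptor
GLN,NE2,donor
GLN,OE1,acceptor
GLU,N,donor
GLU,O,acceptor
GLU,OE1,acceptor
GLU,OE2,acceptor
GLY,N,donor
GLY,O,acceptor
HIS,N,donor
HIS,O,acceptor
HIS,ND1,donor
HIS,ND1,acceptor
HIS,NE2,donor
HIS,NE2,acceptor
ILE,N,donor
ILE,O,acceptor
LEU,N,donor
LEU,O,acceptor
LYS,N,donor
LYS,O,acceptor
LYS,NZ,donor
MET,N,donor
MET,O,acceptor
MET,SD,acceptor
PHE,N,donor
PHE,O,acceptor
PRO,O,acceptor
SER,N,donor
SER,O,acceptor
SER,OG,donor
SER,OG,acceptor
THR,N,donor
THR,O,acceptor
THR,OG1,donor
THR,OG1,acceptor
TRP,N,donor
TRP,O,acceptor
TRP,NE1,donor
TYR,N,donor
TYR,O,acceptor
TYR,OH,donor
TYR,OH,acceptor
VAL,N,donor
VAL,O,acceptor
ALA,OXT,acceptor
ARG,OXT,acceptor
ASN,OXT,acceptor
ASP,OXT,acceptor
CYS,OXT,acceptor
GLN,OXT,acceptor
GLU,OXT,acceptor
GLY,OXT,acceptor
HIS,OXT,acceptor
ILE,OXT,acceptor
LEU,OXT,acceptor
LYS,OXT,acceptor
MET,OXT,acceptor
PHE,OXT,acceptor
PRO,OXT,acceptor
SER,OXT,acceptor
THR,OXT,acceptor
TRP,OXT,acceptor
TYR,OXT,acceptor
VAL,OXT,acceptor
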