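resname,aa,scale
ALA,A,0.62
ARG,R,-2.53
ASN,N,-0.78
ASP,D,-0.90
CYS,C,0.29
GLN,Q,-0.85
GLU,E,-0.74
GLY,G,0.48
HIS,H,-0.40
ILE,I,1.38
LEU,L,1.06
LYS,K,-1.50
MET,M,0.64
PHE,F,1.19
PRO,P,0.12
SER,S,-0.18
THR,T,-0.05
TRP,W,0.81
TYR,Y,0.26
VAL,V,1.08
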