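resname,atom,charge,group
ASP,CG,0.2,carboxylate
ASP,OD1,-0.6,carboxylate
ASP,OD2,-0.6,carboxylate
GLU,CD,0.2,carboxylate
GLU,OE1,-0.6,carboxylate
GLU,OE2,-0.6,carboxylate
LYS,NZ,1.0,amine
ARG,CZ,0.2,guanidine
ARG,NH1,0.4,guanidine
ARG,NH2,0.4,guanidine
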