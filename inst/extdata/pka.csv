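site,pka,charge_when_protonated
D,3.65,0
E,4.25,0
H,6.0,1
K,10.53,1
R,12.48,1
nterm,9.0,1
cterm,3.1,0
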