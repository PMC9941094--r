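resname,atom,charge,group
HIS,ND1,0.5,imidazolium
HIS,NE2,0.5,imidazolium
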