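element,radius,radius_united
H,1.20,1.20
C,1.70,1.90
N,1.55,1.70
O,1.52,1.60
S,1.80,2.00
P,1.80,2.00
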