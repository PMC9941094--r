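atom,charge
N,-0.45
CA,0.45
C,0.45
O,-0.45
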