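element,radius
C,1.85
N,1.75
O,1.65
S,2.00
P,2.10
H,1.00
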