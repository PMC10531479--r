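element,alpha
H,0.387
C,1.283
N,0.964
O,0.637
F,0.296
Cl,2.180
Br,3.013
I,5.415
P,1.538
S,2.900
B,1.600
Si,3.700
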