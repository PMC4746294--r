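label,x,y
Fp1,-0.31,0.95
Fp2,0.31,0.95
AF3,-0.35,0.77
AF4,0.35,0.77
F7,-0.81,0.59
F3,-0.44,0.48
Fz,0.00,0.45
F4,0.44,0.48
F8,0.81,0.59
FC5,-0.66,0.26
FC1,-0.22,0.23
FC2,0.22,0.23
FC6,0.66,0.26
FT8,0.95,0.31
T7,-1.00,0.00
C3,-0.50,0.00
Cz,0.00,0.00
C4,0.50,0.00
T8,1.00,0.00
CP5,-0.66,-0.26
CP1,-0.22,-0.23
CP2,0.22,-0.23
CP6,0.66,-0.26
P7,-0.81,-0.59
P3,-0.44,-0.48
Pz,0.00,-0.45
P4,0.44,-0.48
P8,0.81,-0.59
O1,-0.31,-0.95
Oz,0.00,-1.00
O2,0.31,-0.95
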