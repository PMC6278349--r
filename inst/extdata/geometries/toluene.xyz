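15
toluene generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C          2.49013       -0.00846       -0.01231
C          0.99035        0.00266       -0.00107
C          0.27990        1.20880        0.00134
C         -1.11597        1.20686        0.00298
C         -1.81305       -0.00003        0.00216
C         -1.11461       -1.20602        0.00195
C          0.28119       -1.20552        0.00058
H          2.89909        1.00719        0.00359
H          2.85602       -0.50354       -0.91756
H          2.87128       -0.53705        0.86730
H          0.80847        2.15929        0.00073
H         -1.65936        2.14802        0.00370
H         -2.89968       -0.00038        0.00124
H         -1.65712       -2.14778        0.00166
H          0.81429       -2.15337       -0.00071
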