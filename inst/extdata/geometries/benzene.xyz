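12
benzene generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C          1.38314       -0.22144        0.00537
C          0.50694       -1.30651       -0.00792
C         -0.87093       -1.09053       -0.01470
C         -1.37290        0.21095       -0.00441
C         -0.49670        1.29607        0.01060
C          0.88118        1.07996        0.01366
H          2.45680       -0.38978        0.00923
H          0.89795       -2.32061       -0.01321
H         -1.55354       -1.93593       -0.02737
H         -2.44648        0.37928       -0.00825
H         -0.88777        2.31003        0.01974
H          1.56378        1.92549        0.02297
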