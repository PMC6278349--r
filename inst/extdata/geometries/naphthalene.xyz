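18
naphthalene generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C          2.43164       -0.69590       -0.01079
C          2.43182        0.69595       -0.00404
C          1.22349        1.39402        0.00827
C         -0.00206        0.70776        0.00626
C         -1.22610        1.39541       -0.00132
C         -2.43595        0.69876       -0.01127
C         -2.43690       -0.69296       -0.00540
C         -1.22895       -1.39202        0.00555
C         -0.00270       -0.70639        0.00492
C          1.22204       -1.39323       -0.00029
H          3.37188       -1.24024       -0.02538
H          3.37272        1.24014       -0.01105
H          1.24378        2.48117        0.01546
H         -1.24537        2.48283       -0.00504
H         -3.37572        1.24401       -0.02508
H         -3.37828       -1.23654       -0.01160
H         -1.24984       -2.47933        0.00940
H          1.24237       -2.48076       -0.00273
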