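24
phenanthrene generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C          2.90820       -1.52722        0.04426
C          3.56194       -0.30559        0.01190
C          2.81853        0.87169       -0.01889
C          1.41256        0.84287       -0.01349
C          0.69723        2.04266       -0.01201
C         -0.69487        2.04444        0.01780
C         -1.41338        0.84483        0.02154
C         -2.81798        0.87677        0.05367
C         -3.56501       -0.29803        0.03282
C         -2.91393       -1.52070       -0.02798
C         -1.51743       -1.56563       -0.04592
C         -0.72175       -0.39331       -0.00885
C          0.71865       -0.39458       -0.00093
C          1.51162       -1.56937        0.03147
H          3.47834       -2.45175        0.08129
H          4.64773       -0.26537        0.01649
H          3.34896        1.82121       -0.04009
H          1.21911        2.99776       -0.02175
H         -1.21452        2.99905        0.03416
H         -3.34603        1.82762        0.09535
H         -4.64992       -0.25674        0.05904
H         -3.48635       -2.44408       -0.05991
H         -1.05765       -2.54823       -0.09930
H          1.04936       -2.55190        0.06374
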