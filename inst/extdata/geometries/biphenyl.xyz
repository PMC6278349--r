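22
biphenyl generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C          1.43448       -0.26852        0.03822
C          0.53351       -1.32503       -0.04137
C         -0.84115       -1.07239       -0.12052
C         -1.35214        0.23931       -0.10939
C         -2.80948        0.51319       -0.19039
C         -3.75872       -0.36140        0.37414
C         -5.13205       -0.09771        0.30406
C         -5.59138        1.05483       -0.32402
C         -4.67854        1.93711       -0.89084
C         -3.30780        1.66346       -0.83247
C         -0.41457        1.28617       -0.01660
C          0.96083        1.03844        0.04837
H          2.50199       -0.46287        0.09275
H          0.89699       -2.34933       -0.04709
H         -1.51073       -1.92534       -0.20389
H         -3.44054       -1.26167        0.89433
H         -5.83987       -0.79326        0.74684
H         -6.65618        1.26579       -0.37059
H         -5.02782        2.84063       -1.38312
H         -2.62788        2.36660       -1.30737
H         -0.74584        2.32164        0.01833
H          1.65771        1.87014        0.11074
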