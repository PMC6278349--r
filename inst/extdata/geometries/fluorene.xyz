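23
fluorene generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C         -0.00069        1.84737       -0.03953
C          1.17756        0.89404       -0.02043
C          2.52750        1.20198       -0.00877
C          3.43984        0.14500        0.00777
C          2.99618       -1.18875        0.01014
C          1.63056       -1.49050       -0.00112
C          0.72476       -0.44310       -0.01511
C         -0.72268       -0.44443       -0.01574
C         -1.62788       -1.49224       -0.01158
C         -2.99394       -1.19166       -0.00178
C         -3.43919        0.14143        0.00823
C         -2.52801        1.19943        0.00117
C         -1.17752        0.89312       -0.01548
H         -0.00295        2.43526       -0.96194
H          0.00098        2.48798        0.84726
H          2.87103        2.23102       -0.00954
H          4.50696        0.35386        0.01990
H          3.72493       -1.99583        0.02224
H          1.29792       -2.52269        0.00399
H         -1.29444       -2.52413       -0.01526
H         -3.72185       -1.99968       -0.00022
H         -4.50664        0.34926        0.02056
H         -2.87219        2.22815        0.00911
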