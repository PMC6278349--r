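26
pyrene generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C         -3.51094       -0.03983        0.00669
C         -2.82822        1.17606        0.00889
C         -1.42560        1.20870        0.00136
C         -0.72092        2.42031       -0.00364
C          0.67633        2.43455       -0.00593
C          1.40585        1.23783       -0.00289
C          2.80891        1.23414       -0.00044
C          3.51683        0.03257        0.00047
C          2.83252       -1.18223       -0.00184
C          1.43059       -1.21178       -0.00326
C          0.72678       -2.42350       -0.00516
C         -0.67011       -2.43785       -0.00586
C         -1.39909       -1.24113       -0.00321
C         -2.80138       -1.24017       -0.00166
C         -0.70555       -0.00846       -0.00156
C          0.71128        0.00586       -0.00270
H         -4.59768       -0.05255        0.01150
H         -3.40071        2.10113        0.01715
H         -1.25539        3.36783       -0.00703
H          1.19162        3.39276       -0.01035
H          3.36193        2.17078        0.00170
H          4.60374        0.04272        0.00292
H          3.40298       -2.10823       -0.00190
H          1.26138       -3.37075       -0.00578
H         -1.18499       -3.39596       -0.00724
H         -3.35244       -2.17800       -0.00569
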