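24
anthracene generated idealized geometry (Open Babel gen3d, synthetic stand-in)
C          3.65934       -0.69646       -0.00403
C          3.65974        0.69467        0.00482
C          2.45141        1.39314       -0.00025
C          1.22616        0.70683       -0.00039
C          0.00125        1.39469        0.00183
C         -1.22315        0.70606        0.00264
C         -2.44867        1.39186        0.00125
C         -3.65691        0.69351       -0.00249
C         -3.65604       -0.69823       -0.00099
C         -2.44658       -1.39394        0.00443
C         -1.22269       -0.70572        0.00423
C          0.00164       -1.39324        0.00341
C          1.22566       -0.70470       -0.00320
C          2.44968       -1.39314       -0.01096
H          4.59895       -1.24199       -0.00430
H          4.60071        1.23858        0.01418
H          2.47259        2.48038       -0.00168
H          0.00086        2.48252        0.00261
H         -2.46990        2.47923        0.00164
H         -4.59804        1.23749       -0.00769
H         -4.59589       -1.24345       -0.00481
H         -2.46589       -2.48124        0.00582
H          0.00218       -2.48128        0.00865
H          2.46902       -2.48014       -0.02282
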