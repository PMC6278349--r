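COMPND    geom/benzene.xyz 
AUTHOR    GENERATED BY OPEN BABEL 3.1.0
HETATM    1  C   UNL     1       1.383  -0.221   0.005  1.00  0.00           C  
HETATM    2  C   UNL     1       0.507  -1.307  -0.008  1.00  0.00           C  
HETATM    3  C   UNL     1      -0.871  -1.091  -0.015  1.00  0.00           C  
HETATM    4  C   UNL     1      -1.373   0.211  -0.004  1.00  0.00           C  
HETATM    5  C   UNL     1      -0.497   1.296   0.011  1.00  0.00           C  
HETATM    6  C   UNL     1       0.881   1.080   0.014  1.00  0.00           C  
HETATM    7  H   UNL     1       2.457  -0.390   0.009  1.00  0.00           H  
HETATM    8  H   UNL     1       0.898  -2.321  -0.013  1.00  0.00           H  
HETATM    9  H   UNL     1      -1.554  -1.936  -0.027  1.00  0.00           H  
HETATM   10  H   UNL     1      -2.446   0.379  -0.008  1.00  0.00           H  
HETATM   11  H   UNL     1      -0.888   2.310   0.020  1.00  0.00           H  
HETATM   12  H   UNL     1       1.564   1.925   0.023  1.00  0.00           H  
CONECT    1    2    2    7    6                                       
CONECT    2    3    8    1    1                                       
CONECT    3    9    2    4    4                                       
CONECT    4    3    3   10    5                                       
CONECT    5    4    6    6   11                                       
CONECT    6    1    5    5   12                                       
CONECT    7    1                                                      
CONECT    8    2                                                      
CONECT    9    3                                                      
CONECT   10    4                                                      
CONECT   11    5                                                      
CONECT   12    6                                                      
MASTER        0    0    0    0    0    0    0    0   12    0   12    0
END
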