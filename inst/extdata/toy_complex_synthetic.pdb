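ATOM      1  CA  NEU P   1     -32.725  10.213  14.242  1.00  0.00           C  
ATOM      2  CA  NEU P   2     -30.354   7.372  13.865  1.00  0.00           C  
ATOM      3  CA  BSC P   3     -26.571   6.866  13.453  1.00  0.00           C  
ATOM      4  CA  NEU P   4     -22.744   6.366  13.523  1.00  0.00           C  
ATOM      5  CA  BSC P   5     -18.980   7.078  14.290  1.00  0.00           C  
ATOM      6  CA  BSC P   6     -15.146   6.949  14.736  1.00  0.00           C  
ATOM      7  CA  BSC P   7     -11.361   7.224  14.928  1.00  0.00           C  
ATOM      8  CA  ACD P   8      -7.705   6.355  15.309  1.00  0.00           C  
ATOM      9  CA  BSC P   9      -3.862   7.017  15.814  1.00  0.00           C  
ATOM     10  CA  BSC P  10      -0.263   7.883  14.627  1.00  0.00           C  
ATOM     11  CA  BSC P  11       3.417   8.025  13.845  1.00  0.00           C  
ATOM     12  CA  BSC P  12       7.087   8.415  12.797  1.00  0.00           C  
ATOM     13  CA  NEU P  13      10.858   7.995  12.426  1.00  0.00           C  
ATOM     14  CA  NEU P  14      14.652   7.640  12.233  1.00  0.00           C  
ATOM     15  CA  NEU P  15      18.183   6.911  13.104  1.00  0.00           C  
ATOM     16  CA  ACD P  16      22.060   7.538  12.746  1.00  0.00           C  
ATOM     17  CA  BSC P  17      25.815   6.393  12.474  1.00  0.00           C  
ATOM     18  CA  ACD P  18      29.448   5.542  12.688  1.00  0.00           C  
ATOM     19  CA  NEU P  19      32.422   4.982  15.164  1.00  0.00           C  
ATOM     20  P1  NUC R  20      12.000   0.000   0.000  1.00  0.00           P  
ATOM     21  P1  NUC R  21      11.699   2.670   0.000  1.00  0.00           P  
ATOM     22  P1  NUC R  22      10.812   5.207   0.000  1.00  0.00           P  
ATOM     23  P1  NUC R  23       9.382   7.482   0.000  1.00  0.00           P  
ATOM     24  P1  NUC R  24       7.482   9.382   0.000  1.00  0.00           P  
ATOM     25  P1  NUC R  25       5.207  10.812   0.000  1.00  0.00           P  
ATOM     26  P1  NUC R  26       2.670  11.699   0.000  1.00  0.00           P  
ATOM     27  P1  NUC R  27       0.000  12.000   0.000  1.00  0.00           P  
ATOM     28  P1  NUC R  28      -2.670  11.699   0.000  1.00  0.00           P  
ATOM     29  P1  NUC R  29      -5.207  10.812   0.000  1.00  0.00           P  
ATOM     30  P1  NUC R  30      -7.482   9.382   0.000  1.00  0.00           P  
ATOM     31  P1  NUC R  31      -9.382   7.482   0.000  1.00  0.00           P  
ATOM     32  P1  NUC R  32     -10.812   5.207   0.000  1.00  0.00           P  
ATOM     33  P1  NUC R  33     -11.699   2.670   0.000  1.00  0.00           P  
ATOM     34  P1  NUC R  34     -12.000   0.000   0.000  1.00  0.00           P  
END   
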