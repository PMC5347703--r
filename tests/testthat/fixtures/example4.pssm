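
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
              A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M      -1  -2  -3  -4   0   1   2   3  -5   6   1   0   7  -1  -2  -3   0   1   2   3    0   0   0   0   0   0   0   0   0  29   0   0  71   0   0   0   0   0   0   0  0.61     0.24
    2 A       5  -1   0  -2  -3   1   1   0  -1  -2  -3  -4   0   0   2   3   1  -1  -2  -3   83   0   0   0   0   0   0   0   0   0   0   0   0   0   5  12   0   0   0   0  0.48     0.24
    3 K      -2   2   0   1  -1   3   2  -3   0   1  -1   6  -2  -3  -1   0   1  -4  -2   0    0   8   0   4   0  11   7   0   0   4   0  58   0   0   0   0   8   0   0   0  0.39     0.24
    4 V       0  -3  -3  -3  -1  -2  -2  -3  -3   3   1  -2   1  -1  -2  -2   0  -3  -1   4    5   0   0   0   0   0   0   0   0  22   9   0   4   0   0   0   5   0   0  55  0.33     0.24

                      K         Lambda
Standard Ungapped    0.1337     0.3176
Standard Gapped      0.0410     0.2670
PSI Ungapped         0.1337     0.3176
PSI Gapped           0.0410     0.2670
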