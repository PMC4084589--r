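
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapped real matches to pseudocounts
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M   6  -6  -5  -6  -6  -9  -7  -1   1   7  10  -4   5  10  -5   6   9  -2   0   1    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    2 K  -6  -8   4   9   3   0  -7  -3   9   6   0  -1   0   7  -5   9 -10  -8  -2 -10    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    3 V -10   3   0  -9   9   3   7  -6  -2   7   5   7  -1  -5   9  -7   6   7   9   8    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    4 L  -1   3  -6  -3   7  -9   2 -10   0  -6  -3   2  -1  -5   4   9 -10  10   2  -6    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    5 A  -7 -10   5  -8   4  -9  -6   6  -8   3  -5  10 -10  -9  -9   0  -9   4  -6   4    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    6 A   7  -6   6 -10  -8  -1  -7  -4   5  -3 -10   8   8   9  -1   6  -3   4   0  -5    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    7 C   6  -8   6  -1  -2  -6  -9  -7  -6  -3   2   5   6  -8   1  -2   5   9   4   5    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    8 D   4   2   7   0  -7  -1   7   2   3  10   3   6   3  10  -2   6  -8   5  10  -1    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
    9 E  -4   0  -9   4  -6   6  -8  -1  -6  -7  -6   1   3  -9 -10   2  -6 -10  -9  -4    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00
   10 F  -7   9  -5  -3   2   6   6  -2  -9  -7  -2  -2   4  -5  -9   6   2  -5  -5  -2    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.00 0.00

                      K         Lambda
Standard Ungapped    0.1337     0.3177
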