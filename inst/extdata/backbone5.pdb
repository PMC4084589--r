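HEADER    SYNTHETIC BACKBONE FIXTURE
HETATM    1  O   HOH A 900      99.000  99.000  99.000  1.00  0.00           O
ATOM      2  N   ALA A   1       0.100   0.200   0.300  1.00  0.00           N
ATOM      3  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C
ATOM      4  CA  GLY A   2       3.000   4.000   0.000  1.00  0.00           C
ATOM      5  CA AVAL A   3       6.000   0.000   0.000  0.40  0.00           C
ATOM      6  CA BVAL A   3       6.500   0.500   0.000  0.60  0.00           C
ATOM      7  CA  LEU A   4       9.000   1.000   1.000  1.00  0.00           C
ATOM      8  CA  SER A   5      12.000   2.000   2.000  1.00  0.00           C
END
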