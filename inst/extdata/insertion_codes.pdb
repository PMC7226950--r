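ATOM      1  CA  ALA A  52      11.000  20.000   3.000  1.00  0.00           C
ATOM      2  CA  GLY A  52A     12.500  21.000   4.000  1.00  0.00           C
ATOM      3  CA  SER A  52B     13.250  22.750   5.500  1.00  0.00           C
ATOM      4  CA  LEU A  53      15.000  24.000   6.000  1.00  0.00           C
END
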