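# SYNTHETIC residue-level substitution matrix (stand-in).
# This is NOT the published transmembrane (GPCRtm) matrix: it is BLOSUM62
# with +1 on the hydrophobic diagonal, shipped only so the residue-matrix
# scoring mode can be exercised without external data. Supply the real
# matrix file for production use.
   G  A  V  L  I  P  M  C  F  W  Y  S  T  N  Q  D  E  K  R  H
G  7  0 -3 -4 -4 -2 -3 -3 -3 -2 -3  0 -2  0 -2 -1 -2 -2 -2 -2
A  0  5  0 -1 -1 -1 -1  0 -2 -3 -2  1  0 -2 -1 -2 -1 -1 -1 -2
V -3  0  5  1  3 -2  1 -1 -1 -3 -1 -2  0 -3 -2 -3 -2 -2 -3 -3
L -4 -1  1  5  2 -3  2 -1  0 -2 -1 -2 -1 -3 -2 -4 -3 -2 -2 -3
I -4 -1  3  2  5 -3  1 -1  0 -3 -1 -2 -1 -3 -3 -3 -3 -3 -3 -3
P -2 -1 -2 -3 -3  8 -2 -3 -4 -4 -3 -1 -1 -2 -1 -1 -1 -1 -2 -2
M -3 -1  1  2  1 -2  6 -1  0 -1 -1 -1 -1 -2  0 -3 -2 -1 -1 -2
C -3  0 -1 -1 -1 -3 -1 10 -2 -2 -2 -1 -1 -3 -3 -3 -4 -3 -3 -3
F -3 -2 -1  0  0 -4  0 -2  7  1  3 -2 -2 -3 -3 -3 -3 -3 -3 -1
W -2 -3 -3 -2 -3 -4 -1 -2  1 12  2 -3 -2 -4 -2 -4 -3 -3 -3 -2
Y -3 -2 -1 -1 -1 -3 -1 -2  3  2  8 -2 -2 -2 -1 -3 -2 -2 -2  2
S  0  1 -2 -2 -2 -1 -1 -1 -2 -3 -2  4  1  1  0  0  0  0 -1 -1
T -2  0  0 -1 -1 -1 -1 -1 -2 -2 -2  1  5  0 -1 -1 -1 -1 -1 -2
N  0 -2 -3 -3 -3 -2 -2 -3 -3 -4 -2  1  0  6  0  1  0  0  0  1
Q -2 -1 -2 -2 -3 -1  0 -3 -3 -2 -1  0 -1  0  5  0  2  1  1  0
D -1 -2 -3 -4 -3 -1 -3 -3 -3 -4 -3  0 -1  1  0  6  2 -1 -2 -1
E -2 -1 -2 -3 -3 -1 -2 -4 -3 -3 -2  0 -1  0  2  2  5  1  0  0
K -2 -1 -2 -2 -3 -1 -1 -3 -3 -3 -2  0 -1  0  1 -1  1  5  2 -1
R -2 -1 -3 -2 -3 -2 -1 -3 -3 -3 -2 -1 -1  0  1 -2  0  2  5  0
H -2 -2 -3 -3 -3 -2 -2 -3 -1 -2  2 -1 -2  1  0 -1  0 -1  0  8
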