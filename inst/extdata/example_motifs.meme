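MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF WBOX_synthetic
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.020000 0.030000 0.050000 0.900000
0.010000 0.010000 0.020000 0.960000
0.050000 0.050000 0.850000 0.050000
0.900000 0.040000 0.030000 0.030000
0.050000 0.880000 0.040000 0.030000
0.050000 0.450000 0.050000 0.450000

MOTIF GBOX_synthetic
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.050000 0.850000 0.050000 0.050000
0.900000 0.030000 0.040000 0.030000
0.030000 0.870000 0.050000 0.050000
0.050000 0.050000 0.870000 0.030000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.870000 0.030000

MOTIF LOWINFO_synthetic
letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0
0.250000 0.250000 0.250000 0.250000
0.400000 0.100000 0.100000 0.400000
0.250000 0.250000 0.250000 0.250000
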