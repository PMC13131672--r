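MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF SYN0001 SYNTH_NR_HALF
letter-probability matrix: alength= 4 w= 6 nsites= 50 E= 0
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.850000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000

MOTIF SYN0002 SYNTH_CEBP_LIKE
letter-probability matrix: alength= 4 w= 8 nsites= 50 E= 0
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.050000 0.850000
 0.700000 0.100000 0.100000 0.100000
 0.100000 0.700000 0.100000 0.100000
 0.100000 0.100000 0.700000 0.100000
 0.100000 0.600000 0.100000 0.200000
 0.700000 0.100000 0.100000 0.100000
 0.100000 0.700000 0.100000 0.100000

MOTIF SYN0003 SYNTH_FOX_LIKE
letter-probability matrix: alength= 4 w= 7 nsites= 50 E= 0
 0.100000 0.100000 0.100000 0.700000
 0.100000 0.100000 0.700000 0.100000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.050000 0.850000
 0.100000 0.100000 0.700000 0.100000
 0.700000 0.100000 0.100000 0.100000
 0.100000 0.100000 0.100000 0.700000
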