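MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.3 C 0.2 G 0.2 T 0.3

MOTIF MEME1 TOYMEME
letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0
 1.000000 0.000000 0.000000 0.000000
 0.000000 1.000000 0.000000 0.000000
 0.000000 0.000000 1.000000 0.000000

MOTIF MEME2 TOYMEME2
letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0
 0.700000 0.100000 0.100000 0.100000
 0.100000 0.700000 0.100000 0.100000
 0.100000 0.100000 0.700000 0.100000
 0.100000 0.100000 0.100000 0.700000
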