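>SYN0002.1 GATA_like_synthetic
A  [  12   9  812  44 903   12 890  16  35 104  60 ]
C  [ 310  33   10  19   3    8   2  11 340 180 183 ]
G  [  88 855   25  17   4  880   6  22 310 420 402 ]
T  [ 502  15   65 832   2   12  14 863 227 208 267 ]
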