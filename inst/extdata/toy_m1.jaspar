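>TOYM2 ACG_TOY
A  [ 10 0 0 ]
C  [ 0 10 0 ]
G  [ 0 0 10 ]
T  [ 0 0 0 ]
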