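>SYN0001.1 CTCF_like_synthetic
A  [  87  167  281   56    8  744   40  107  851    5  333   54   12   56  104  372   82  117  402 ]
C  [ 291  145   49  800  903   13  528  433   11    0    3  12    0    8  733   13  482  322  181 ]
G  [  76  414  449   21    0   65  334   48   32 1620   76 1277 1192  1621   12 1712   8  720  291 ]
T  [ 459  187  134   36    2   91   11  324   18    9 1502   71  718    0   29   31 1356  109  254 ]
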