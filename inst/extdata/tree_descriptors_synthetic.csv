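compound_id,X4sol,VR2_Dzi
3,7.102,11.215
4,7.254,11.487
5,7.398,11.342
6,7.051,11.903
7,7.902,12.384
8,7.305,12.066
9,7.748,11.296
10,7.951,12.014
11,8.412,11.108
12,8.603,12.592
13,8.127,11.463
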