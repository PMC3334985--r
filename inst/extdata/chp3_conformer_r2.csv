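conformer,r2_hb,r2_vdw,similarity
1,0.69,0.70,0.69
2,0.50,0.59,0.53
3,0.89,0.57,0.79
5,0.66,0.55,0.62
6,0.53,0.40,0.49
7,0.70,0.55,0.65
8,0.72,0.58,0.68
9,0.75,0.79,0.76
10,0.95,0.63,0.85
11,0.87,0.69,0.82
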