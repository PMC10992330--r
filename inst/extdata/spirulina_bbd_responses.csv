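"run_id","pigment_mg_per_g","abts_mg_TRE_per_g","tpc_mg_GAE_per_g"
1,65.88,27.41,23.15
2,63.37,35.36,7.17
3,66.77,26.93,23.7
4,39.84,30.48,21.98
5,30.08,21.27,14.6
6,18.5,28.92,12.35
7,57.35,27.67,5.73
8,39.92,34.49,4.72
9,64.81,21.73,22.39
10,106.31,25.82,39.99
11,161.04,34.4,43.49
12,83.87,35.05,41.82
13,94.95,27.14,27.97
14,25.1,29.93,31.14
15,60.57,31.25,29.49
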