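"run_id","temperature_C","time_min","ratio_mL_per_mg","x1","x2","x3"
1,50,20,60,-1,-1,0
2,70,20,60,1,-1,0
3,50,40,60,-1,1,0
4,70,40,60,1,1,0
5,50,30,50,-1,0,-1
6,70,30,50,1,0,-1
7,50,30,70,-1,0,1
8,70,30,70,1,0,1
9,60,20,50,0,-1,-1
10,60,40,50,0,1,-1
11,60,20,70,0,-1,1
12,60,40,70,0,1,1
13,60,30,60,0,0,0
14,60,30,60,0,0,0
15,60,30,60,0,0,0
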