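run,pure_water_px,calibrator_px,sample1_px,sample2_px
1,15831,16403,16144,16308
2,15869,16164,15757,16205
3,15912,15922,16417,15838
4,16006,16193,15792,16035
5,15918,16404,16080,16173
6,16298,16016,16292,16227
7,16431,16167,16242,15923
8,15869,16084,15883,16367
9,15933,15979,16344,15827
10,15957,16127,15899,16061
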