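velocity_mm_s,depth_2,depth_2.1,depth_2.2,depth_2.3,depth_2.4,depth_3
100,13.27,16.26,18.10,23.75,31.42,61.72
150,13.53,17.52,18.25,25.00,31.26,60.79
400,18.09,25.89,20.45,27.31,32.27,68.18
1000,25.25,35.57,27.57,31.57,38.75,75.53
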