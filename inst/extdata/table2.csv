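run,depth_2,depth_2.1,depth_2.2,depth_2.3,depth_2.4,depth_3
1,13.15,16.42,18.11,23.64,31.45,61.79
2,12.89,16.27,17.94,23.75,31.51,61.91
3,13.12,16.33,18.24,23.91,31.27,61.58
4,13.21,16.24,17.91,23.77,31.36,61.66
5,13.23,15.99,18.06,23.52,31.23,61.73
6,12.94,16.04,18.25,23.73,31.35,61.89
7,13.29,16.15,18.04,23.89,31.57,61.70
8,12.77,16.29,18.27,23.66,31.47,61.69
9,13.36,16.18,18.16,23.93,31.39,61.52
10,13.45,16.36,18.33,23.55,31.55,61.61
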