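sample_no,intensity_mass5040,intensity_mass8490,intensity_mass9980,volume_nl
1,58.88,34.57,29.45,101.97
2,57.63,35.52,30.21,101.57
3,60.15,35.02,30.17,99.78
4,59.56,34.32,29.91,101.73
5,59.71,35.29,30.89,102.87
6,58.92,35.97,30.98,100.04
7,59.85,35.20,29.63,103.71
8,60.18,34.45,29.72,100.65
9,60.52,34.42,30.82,101.52
10,59.73,35.16,29.31,103.01
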