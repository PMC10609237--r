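name,density_kg_m3,viscosity_pa_s,contact_angle_deg
Water,997.04,0.0009,86.3
Calibrator,996.81,0.0009,86.5
Sample 1,1134.91,0.0013,34.2
Sample 2,1467.62,0.0024,15.1
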