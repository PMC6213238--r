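dx_percent,v_gas_ml,temp_c,pressure_pa,mass_kg,dt_h
1,100,25,101325,0.05,24
0.8,100,25,101325,0.05,24
1.2,100,25,101000,0.05,22
0.9,100,25,101000,0.05,26
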