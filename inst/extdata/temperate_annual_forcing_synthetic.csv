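time_h,temp_c
0,-7.54
730,-7.51
1460,-3.86
2190,2.43
2920,9.67
3650,15.93
4380,19.54
5110,19.51
5840,15.86
6570,9.57
7300,2.33
8030,-3.93
8760,-7.54
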