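frequency,duration_class,fm_v_lt_75,fm_v_ge_75
0.2,1h,1.00,1.00
0.5,1h,0.97,0.97
1,1h,0.94,0.94
2,1h,0.91,0.91
3,1h,0.88,0.88
4,1h,0.84,0.84
0.2,2h,0.95,0.95
0.5,2h,0.92,0.92
1,2h,0.88,0.88
2,2h,0.84,0.84
3,2h,0.79,0.79
4,2h,0.72,0.72
0.2,8h,0.85,0.85
0.5,8h,0.81,0.81
1,8h,0.75,0.75
2,8h,0.66,0.66
3,8h,0.55,0.55
4,8h,0.45,0.45
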