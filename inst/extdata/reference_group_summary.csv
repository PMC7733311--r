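picture,t_sum_count,t_sum_duration,optimal_k,best_p_count,best_p_duration
P1,8.26,16.35,11,0.114,0.001
P2,8.54,13.65,14,0.071,0.038
P3,9.81,13.08,12,0.853,0.041
P4,7.00,10.96,12,0.229,0.022
P5,4.98,11.54,12,0.047,0.055
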