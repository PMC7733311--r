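cluster,count_expert,count_layman,p_count,duration_expert,duration_layman,p_duration
1,13.6,18.3,0.07,214.3,191.7,0.33
2,10.9,9.4,0.37,192.1,167.9,0.11
3,4.9,6.58,0.17,178.8,185.1,0.56
4,4.6,5.26,0.47,218.8,171.2,0.14
5,3.9,4.47,0.72,117,158.7,0.77
6,3.5,3.89,0.76,164.4,184.2,0.75
7,3.3,3.58,0.76,166.8,117.1,0.18
8,3.15,2.47,0.61,126.4,101.1,0.21
9,2.55,2.32,0.75,143.8,108.3,0.10
10,1.45,1.95,0.47,119.3,128.1,0.04
11,1.35,1.79,0.45,128.0,128.1,0.30
12,0.85,0.74,0.80,44.9,50.6,0.52
13,0.7,0.68,0.96,60.7,54.5,0.98
14,0.65,0.37,0.45,44,18.7,0.42
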