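time,event,x
0.21,1,1.42
0.35,2,-0.23
0.48,0,0.87
0.52,1,0.66
0.77,1,1.95
0.84,2,-1.12
0.91,0,0.35
1.02,2,0.12
1.15,1,-0.48
1.33,0,-0.91
1.48,2,0.44
1.62,1,1.05
1.75,0,-0.17
1.91,2,-1.53
2.10,1,0.78
2.34,2,0.03
2.55,0,-0.62
2.81,1,-0.29
3.05,2,-2.01
3.42,0,0.55
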