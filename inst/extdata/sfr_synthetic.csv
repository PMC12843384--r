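"z","rate"
11.31966,0.0504907
6.27864,0.199794
4.43969,0.415499
3.44053,0.637751
2.79768,0.821081
2.3426,0.937752
1.99988,1.04393
1.7303,0.906219
1.51126,0.855057
1.32878,0.711416
1.17368,0.65641
1.03969,0.598688
0.92234,0.474855
0.81839,0.434769
0.72539,0.386714
0.64148,0.350468
0.56521,0.301925
0.49543,0.249021
0.43122,0.221966
0.37183,0.220044
0.31666,0.185591
0.26519,0.157248
0.21699,0.146146
0.17172,0.134922
0.12906,0.121951
0.08877,0.100723
0.0506,0.0896649
0.01438,0.0759004
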