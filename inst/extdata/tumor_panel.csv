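sample,subtype,qrt_pcr,western_blot,ihc_h_score
1,SCC,0.50,0.01,0
2,AC,2.95,0.03,35
3,AC,3.77,0.01,0
4,AC,3.94,0.04,35
5,AC,4.00,0.02,130
6,SCC,4.41,0.04,30
7,AC,6.10,0.02,55
8,SCC,6.48,0.17,120
9,AC,6.82,0.04,107
10,AC,7.20,0.03,82
11,SCC,7.29,0.10,30
12,SCC,7.53,0.13,120
13,SCC,10.35,0.05,72
14,AC,10.91,0.01,224
15,SCC,11.80,0.04,75
16,SCC,14.51,0.04,113
17,SCC,15.32,0.09,105
18,SCC,15.53,0.10,137
19,AC,16.00,0.04,135
20,AC,22.26,0.01,175
21,AC,26.56,0.06,65
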