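subtype,ihc_h_score,ctc_per_ml,ctc_h_score,cluster_weighted_h_score,burden_per_ml,cluster_weighted_burden_per_ml,pct_negative
AC,0,32,47,64,69,210,53
SCC,0,71,74,102,268,788,35
AC,2,10,38,45,15,26,63
AC,3,8,138,138,106,106,38
AC,10,3,0,0,7,7,75
SCC,14,65,29,51,82,273,74
AC,20,9,12,12,3,3,88
AC,20,0,0,0,0,0,NA
SCC,20,346,35,49,506,1018,68
AC,30,13,61,78,35,100,39
AC,31,58,97,110,269,924,9
AC,31,33,74,108,118,448,35
AC,33,34,78,98,128,353,28
AC,35,71,47,63,129,221,54
AC,35,28,15,21,17,31,85
SCC,36,7,20,17,4,4,80
AC,38,39,43,44,56,89,57
AC,45,14,24,36,12,28,76
AC,50,1,0,0,0,0,100
AC,50,247,69,99,784,2945,37
SCC,56,1,0,0,4,4,0
AC,60,0,0,0,0,0,NA
AC,60,2,0,0,89,89,0
SCC,61,16,63,64,149,167,47
AC,65,22,19,42,19,56,85
AC,70,8,86,89,31,43,14
AC,73,25,81,97,79,182,24
SCC,82,200,47,67,382,1176,54
SCC,91,2,0,0,21,21,50
AC,115,0,0,0,0,0,NA
SCC,130,94,68,82,397,615,53
AC,140,125,67,98,389,1013,42
AC,140,35,33,42,71,122,74
AC,150,45,36,53,68,172,64
SCC,169,4,0,33,7,7,50
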