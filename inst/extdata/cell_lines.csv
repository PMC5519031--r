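cell_line,qrt_pcr,western_blot,icc_rank
H226,5.11,1.00,4
H1975,1.24,0.09,3
H2122,1.09,0.10,2
H460,0.02,0.00,1
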