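cell_count,death_rate,ploidy,factor
1.5e+11,0.0015,2,1.6
4.5e+10,0.001,4,1.6
5e+09,5e-04,8,1.6
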