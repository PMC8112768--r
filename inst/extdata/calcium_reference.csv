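sex,age_min,age_max,status,ear,ul
F,18,50,none,800,2500
F,50,150,none,1000,2000
M,18,70,none,800,2500
M,70,150,none,1000,2000
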