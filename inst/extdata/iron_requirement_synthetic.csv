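p,q_absorbed
0.025,0.80
0.05,0.88
0.10,0.99
0.25,1.22
0.50,1.52
0.75,1.95
0.90,2.55
0.95,3.10
0.975,3.80
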