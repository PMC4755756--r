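"turnover","x2B","x5A","x3A"
2,0.95,0.03,0.01
46,0.8,0.1,0.05
341,0.55,0.22,0.12
921,0.38,0.28,0.18
1785,0.25,0.25,0.18
2141,0.2,0.22,0.16
5361,0.02,0.05,0.04
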