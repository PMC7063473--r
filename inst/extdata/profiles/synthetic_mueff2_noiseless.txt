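# synthetic noiseless exponential profile, T(z) = exp(-2 z)
# ground truth mu_eff = 2 mm^-1
# z_mm transmittance
0 1
0.05 0.90483741803596
0.1 0.818730753077982
0.15 0.740818220681718
0.2 0.670320046035639
0.25 0.606530659712633
0.3 0.548811636094026
0.35 0.496585303791409
0.4 0.449328964117222
0.45 0.406569659740599
0.5 0.367879441171442
0.55 0.33287108369808
0.6 0.301194211912202
0.65 0.272531793034013
0.7 0.246596963941606
0.75 0.22313016014843
0.8 0.201896517994655
0.85 0.182683524052735
0.9 0.165298888221587
0.95 0.149568619222635
1 0.135335283236613
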