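# polarTrack logistic classifier v1
threshold	0.5
(Intercept)	-97.607253930928337
max_ratio	-5.2125650139237729
peak_med	0.019794771360899483
pole_frac	217.63976470022456
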