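time,px,py,angle,opening
0,0.055,0.023,0,0.001
0.2,0.075,0.023,0,0.001
0.25,0.075,0.023,0,0.01
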