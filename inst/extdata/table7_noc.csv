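frequency_hz,resistance,reactance
3,0.86,-0.41
5,0.71,-0.33
10,0.54,-0.21
15,0.42,-0.12
20,0.40,0.02
25,0.46,0.12
35,0.59,0.21
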