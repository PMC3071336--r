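frequency_hz,resistance,reactance
3,0.86,-0.40
5,0.72,-0.32
10,0.55,-0.21
15,0.43,-0.12
20,0.41,0.02
25,0.47,0.11
35,0.59,0.20
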