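"value","frequency"
1,1000
2,330
4,172
8,109
16,76
30,57
60,44
100,36
180,30
300,25
450,22
600,19
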