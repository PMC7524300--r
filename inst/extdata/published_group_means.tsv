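feature	BB	BP	TF	ASF
Shannon Index	1.7	2	2.3	2.4
Richness	29	37	44	52
Evenness	0.51	0.56	0.6	0.62
Sequence reads	26278	27025	25480	25094
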