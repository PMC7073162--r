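id	l1	l2	l3
l1	1	0.2	0.5
l2	0.2	1	0.4
l3	0.5	0.4	1
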