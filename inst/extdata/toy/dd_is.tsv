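id	d1	d2	d3
d1	1	0.2	0.5
d2	0.2	1	0.4
d3	0.5	0.4	1
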