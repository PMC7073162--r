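d2	d1
d3	d1
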