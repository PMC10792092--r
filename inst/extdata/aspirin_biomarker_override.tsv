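index	action
37	include
45	include
43	exclude
110	exclude
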