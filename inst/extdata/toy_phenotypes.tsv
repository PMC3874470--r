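id	disease	trait
ind1	1	31.5
ind2	0	24.2
ind3	1	28.9
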