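id	SNP1	SNP2
ind1	0	2
ind2	1	1
ind3	2	0
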