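gene	protein_change	count
CTNNB1	p.S45F	8
KRAS	p.A59T	2
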