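gene	sample_id	variant_class	protein_change
TP53	S01	stopgain	p.R213*
TP53	S02	frameshift_indel	p.P72fs
CTNNB1	S01	missense	p.S45F
CTNNB1	S03	missense	p.S45F
KRAS	S02	missense	p.A59T
EGFR	S04	other	p.L858=
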