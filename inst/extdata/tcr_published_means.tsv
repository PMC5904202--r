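kind	name	mean
tcr	F11	8.7
tcr	HA1.7	9.0
tcr	003	6.4
loop	CDR1a	7.2
loop	CDR2a	7.7
loop	Fwa	8.7
loop	CDR3a	10.2
loop	CDR1b	7.2
loop	CDR2b	5.5
loop	Fwb	5.8
loop	CDR3b	12.2
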