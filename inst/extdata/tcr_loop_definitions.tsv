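tcr	loop_name	chain_id	start	end	amplitude
F11	CDR1a	A	25	30	7.7
F11	CDR2a	A	49	54	9.4
F11	Fwa	A	66	72	8.4
F11	CDR3a	A	93	98	10.6
F11	CDR1b	B	23	29	8.3
F11	CDR2b	B	48	53	6.5
F11	Fwb	B	66	72	6.5
F11	CDR3b	B	92	98	12.2
HA1.7	CDR1a	A	25	30	8.0
HA1.7	CDR2a	A	49	54	6.9
HA1.7	Fwa	A	66	72	11.0
HA1.7	CDR3a	A	93	101	9.9
HA1.7	CDR1b	B	26	31	9.0
HA1.7	CDR2b	B	49	54	6.9
HA1.7	Fwb	B	69	74	6.1
HA1.7	CDR3b	B	96	102	14.9
003	CDR1a	A	27	34	6.0
003	CDR2a	A	52	57	6.8
003	Fwa	A	68	74	6.8
003	CDR3a	A	95	100	10.2
003	CDR1b	B	27	32	4.4
003	CDR2b	B	50	55	3.0
003	Fwb	B	69	74	4.8
003	CDR3b	B	95	102	9.4
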