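tcr	pdb_id	crystal	space_group	resolution	a	b	c	alpha	beta	gamma
F11	6FR9	003	P 21 21 2	1.62	85.5	115.4	50.9	90.0	90.0	90.0
F11	6FRA	011	P 21 21 2	1.73	85.7	114.6	50.7	90.0	90.0	90.0
F11	6EH7	034	P 21 21 2	1.89	85.4	114.5	50.6	90.0	90.0	90.0
F11	6FRB	036	P 21 21 2	1.75	85.2	115.4	50.5	90.0	90.0	90.0
F11	6EH6	041	P 21 21 2	1.78	85.8	114.1	50.7	90.0	90.0	90.0
F11	6FRC	046	P 21 21 2	1.59	85.3	114.8	50.7	90.0	90.0	90.0
F11	6FUM	053	P 21 21 2	1.76	85.6	114.2	50.6	90.0	90.0	90.0
F11	6FUN	054	P 21 21 2	1.58	85.1	115.3	50.7	90.0	90.0	90.0
F11	6FUO	055	P 21 21 2	1.70	85.4	115.2	50.8	90.0	90.0	90.0
F11	6FUP	058	P 21 21 2	1.72	85.3	115.2	50.7	90.0	90.0	90.0
F11	6FUQ	061	P 21 21 2	1.60	85.4	114.8	50.7	90.0	90.0	90.0
F11	6FUR	081	P 21 21 1	1.73	50.7	114.9	85.3	90.0	91.1	90.0
HA1.7	6FR6	010	P 1 21 1	2.98	70.0	50.2	73.2	90.0	93.3	90.0
HA1.7	6FR7	049	P 1 21 1	2.31	69.4	50.0	72.8	90.0	94.5	90.0
HA1.7	6FR8	054	P 1 21 1	2.38	69.5	49.9	72.9	90.0	94.3	90.0
HA1.7	6EH8	077	P 1 21 1	2.51	69.2	49.5	72.6	90.0	94.7	90.0
HA1.7	6EH9	079	P 1 21 1	2.49	69.5	50.0	72.8	90.0	93.1	90.0
003	6FR3	007	P 1 21 1	1.35	43.1	81.4	64.8	90.0	90.1	90.0
003	6FR4	035	P 1 21 1	1.28	43.3	81.3	65.1	90.0	90.3	90.0
003	6EH4	037	P 1 21 1	1.26	43.2	81.2	65.1	90.0	90.3	90.0
003	6FR5	041	P 1 21 1	1.37	43.1	81.2	64.8	90.0	90.4	90.0
003	6EH5	042	P 1 21 1	1.29	43.2	81.2	64.9	90.0	90.3	90.0
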