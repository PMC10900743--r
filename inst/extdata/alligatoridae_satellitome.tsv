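# Alligatoridae satellitome summary (39 satDNA families, 5 species).
# Columns: species = 3-letter code; sf = intraspecific superfamily (blank
# for singletons); rul = repeat unit length (nt); at_percent = A+T content;
# abundance_percent = genomic abundance; divergence_percent = Kimura
# divergence; tsi = tandem structure index; group = interspecific
# similarity group at >= 50% (blank = ungrouped).
# Known discrepancies in the source report, left as printed in its table:
# ClaSat13-398 TSI is 0.41 here but 0.21 in the running text;
# ClaSat02-6317 TSI is 0.87 here but 0.74 in the running text.
species	sf	name	rul	at_percent	abundance_percent	divergence_percent	tsi	group
Cya	1	CyaSat01-41	41	63.4	2.21	18.79	0.91	1
Cya		CyaSat02-40	40	50.0	0.212	8.35	0.98	3
Cya	2	CyaSat03-60	60	41.7	0.099	18.50	0.98	2
Cya	1	CyaSat04-41	41	58.5	0.084	21.64	0.89	1
Cya	2	CyaSat05-200	200	43.5	0.062	8.67	0.96	2
Cya	1	CyaSat06-286	286	57.3	0.061	4.29	0.61	1
Cla	1	ClaSat01-41	41	46.3	1.077	11.70	0.93	1
Cla		ClaSat02-6317	6317	51.0	0.733	7.94	0.87
Cla	2	ClaSat03-183	183	40.4	0.268	9.30	0.87	2
Cla		ClaSat04-536	536	26.1	0.262	4.83	0.9	4
Cla		ClaSat05-40	40	47.5	0.207	9.51	0.87	3
Cla	1	ClaSat06-1063	1063	53.3	0.181	9.09	0.74	1
Cla	1	ClaSat07-320	320	53.1	0.129	8.40	0.89	1
Cla	1	ClaSat08-800	800	55.9	0.129	14.84	0.99	1
Cla	1	ClaSat09-285	285	46.5	0.074	3.90	0.95	1
Cla	2	ClaSat10-60	60	40.0	0.069	17.79	0.42	2
Cla	1	ClaSat11-547	547	51.7	0.069	9.81	0.69	1
Cla	2	ClaSat12-24	24	33.3	0.053	16.21	0.82	2
Cla		ClaSat13-398	398	32.7	0.042	8.61	0.41
Mni	1	MniSat01-41	41	58.5	1.582	8.99	0.87	1
Mni	1	MniSat02-246	246	55.7	0.442	5.54	0.74	1
Mni		MniSat03-60	60	40.0	0.240	17.03	0.96	2
Mni		MniSat04-40	40	52.5	0.110	11.23	0.97	3
Mni	1	MniSat05-248	248	55.6	0.045	10.56	0.57	1
Mni	1	MniSat06-41	41	56.1	0.032	18.32	0.90	1
Ptr	1	PtrSat01-41	41	41.5	1.092	5.02	0.91	1
Ptr	2	PtrSat02-24	24	37.5	0.705	10.34	0.98	2
Ptr	1	PtrSat03-147	147	55.1	0.594	10.02	0.95	1
Ptr	1	PtrSat04-99	99	51.5	0.332	4.07	0.72	1
Ptr	1	PtrSat05-41	41	53.7	0.328	12.86	0.92	1
Ptr	2	PtrSat06-100	100	45.0	0.252	9.69	0.97	2
Ptr	1	PtrSat07-41	41	56.1	0.155	16.09	0.96	1
Ptr	3	PtrSat08-214	214	28.0	0.140	1.05	0.57	3
Ptr		PtrSat09-490	490	31.6	0.112	4.29	0.96	4
Ptr	3	PtrSat10-40	40	45.0	0.112	12.41	0.38	3
Ptr	1	PtrSat11-23	23	52.2	0.028	13.70	0.05	1
Asi		AsiSat01-1717	1717	50.6	0.234	13.39	0.95
Asi		AsiSat02-60	60	38.3	0.154	3.51	0.99
Asi		AsiSat03-96	96	34.4	0.02	9.25	0.93	3
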