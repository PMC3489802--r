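name	chrom	map_position_mb	size_mb	cytoband	p_value	freq_total_pct	freq_stageI_pct	freq_stageII_pct	event
RAR-G1	1	143.83-144.30	0.47	q21.1	0.04	48	36	51	Earlier
RAR-G2	1	148.12-150.25	2.13	q21.2-q21.3	0.01	50	36	54	Earlier
RAR-G3	1	150.75-155.11	4.36	q21.3-q23.1	0.04	48	36	51	Earlier
RAR-G4	1	158.48-159.47	0.99	q23.2-q23.3	0.04	48	45	49	Earlier
RAR-G5	1	226.10-226.90	0.80	q24.13	0.04	48	45	49	Earlier
RAR-G6	6	64.05-64.75	0.70	q12	0.00	38	45	35	Earlier
RAR-G7	8	123.47-124.74	1.27	q24.13	0.02	50	36	54	Earlier
RAR-G8	8	126.23-127.30	1.07	q24.13-q24.21	0.02	50	36	54	Earlier
RAR-G9	8	140.69-143.86	3.17	q24.3	0.02	50	36	54	Earlier
RAR-G10	8	144.34-146.27	1.93	q24.3	0.02	50	36	54	Earlier
RAR-G11	16	0-3.22	3.22	p13.3	0.05	38	27	41	UC
RAR-G12	16	28.32-31.19	2.87	p11.2	0.05	40	36	41	Earlier
RAR-G13	17	34.97-35.30	0.33	q12	0.03	38	36	38	Earlier
RAR-G14	17	70.76-71.21	0.45	q25.1	0.03	38	9	46	Later
RAR-G15	17	76.90-78.77	1.87	q25.3	0.03	38	9	46	Later
RAR-G16	20	43.84-44.15	0.31	q13.12	0.00	33	18	38	UC
RAR-G17	20	60.17-61.61	1.44	q13.33	0.04	31	18	35	UC
RAR-G18	20	61.67-62.44	0.77	q13.33	0.04	31	27	32	UC
RAR-L1	8	8.14-14.07	5.93	p23.1-p22	0.00	50	36	54	Earlier
RAR-L2	8	15.66-17.12	1.44	p22	0.02	48	36	51	Earlier
RAR-L3	8	24.01-26.72	2.71	p21.2	0.02	48	36	51	Earlier
RAR-L4	16	75.79-80.74	4.95	q23.1-q23.3	0.00	33	27	35	UC
RAR-L5	17	10.54-14.10	3.56	p13.1-p12	0.04	44	27	49	UC
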