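snp	chrom	pos	gene	gene_flag	allele_d	allele_r	y_dd	f_dd	y_rd	f_rd	y_rr	f_rr	delta	log10p_dom	ni
rs111023007	4	23542497	AGMO	u	C	A	11.89	0.858	13.19	0.137	10.53	0.005	1.75	26.62	-2.00
rs29023731	4	23863959	AGMO	in	A	C	11.91	0.852	13.07	0.143	10.71	0.005	1.56	23.01	-1.77
rs110384471	5	23955328	PLXNC1	in	G	A	12.26	0.858	11.07	0.138	7.36	0.005	1.17	12.08	-4.31
rs135494774	5	25556149	NCKAP1L	in	G	A	12.34	0.831	11.01	0.162	7.52	0.007	0.99	12.06	-4.15
rs109675908	5	26499453	ATF7	in	A	G	12.29	0.841	10.99	0.153	7.34	0.006	1.07	12.67	-4.30
rs110558219	5	26715326	AAAS	in	G	A	12.26	0.859	11.00	0.137	6.25	0.004	1.64	21.69	-5.38
rs109438971	5	26964045	EIF4B-KRT18	between	A	G	12.26	0.859	11.01	0.137	6.22	0.004	1.66	22.42	-5.41
rs41884737	18	43786051	CEBPA-CEBPG	between	G	A	12.25	0.851	11.21	0.143	5.96	0.006	1.83	34.67	-5.77
rs41885943	18	43854199	PEPD	in	G	A	12.25	0.848	11.23	0.146	6.12	0.006	1.79	34.41	-5.62
rs133443778	18	43887966	PEPD	in	G	A	12.29	0.851	11.27	0.143	6.06	0.006	1.83	32.09	-5.72
rs43746558	18	44167440	CHST8	in	G	A	12.29	0.855	11.27	0.140	5.65	0.005	2.01	37.65	-6.13
rs133467479	23	15731441	CCND3	in	G	A	12.34	0.792	11.34	0.196	8.84	0.012	0.71	9.90	-3.00
rs136501931	23	18370790	SUPT3H	in	G	A	12.27	0.840	11.44	0.153	8.22	0.007	1.17	15.70	-3.63
rs109383912	24	26114907	DSC3	in	G	A	12.09	0.858	12.04	0.137	8.13	0.005	1.88	33.25	-3.94
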