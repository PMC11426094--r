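snp	chrom	pos	gene	gene_flag	effect	al_pos	ae_pos	f_pos	al_neg	ae_neg	f_neg	log10p_add
rs133886272	2	126156967	LOC104971349-FAM46B	between	-0.42	2	0.137	0.673	1	-0.282	0.327	39.18
rs41255335	3	23565194	PHGDH	in	0.39	1	0.184	0.529	2	-0.207	0.471	40.63
rs110527224	6	86860291	SLC4A4	d	-0.45	2	0.158	0.649	1	-0.293	0.351	49.84
rs110380398	6	86877334	SLC4A4	d	0.45	1	0.158	0.649	2	-0.293	0.351	49.38
rs109452259	6	87068809	GC-NPFFR2	between	0.42	1	0.181	0.572	2	-0.242	0.428	47.15
rs137147462	6	87153414	GC-NPFFR2	between	-0.39	2	0.181	0.539	1	-0.212	0.461	40.91
rs110434046	6	87184768	GC-NPFFR2	between	-0.44	2	0.159	0.635	1	-0.277	0.365	46.96
rs109034709	6	87316810	NPFFR2	in	-0.43	2	0.156	0.635	1	-0.272	0.365	45.38
rs109793149	6	88808252	CXCL8	u	0.57	1	0.082	0.857	2	-0.490	0.143	42.71
rs41588974	6	91406353	SHROOM3	in	-0.43	2	0.116	0.732	1	-0.317	0.268	39.33
rs137178400	10	33756427	TMCO5A-SPRED1	between	-0.41	2	0.173	0.581	1	-0.240	0.419	43.48
rs41647633	10	33940919	SPRED1	in	-0.43	2	0.121	0.717	1	-0.307	0.283	39.66
rs110578748	10	34000269	SPRED1	d	-0.40	2	0.176	0.556	1	-0.220	0.444	41.23
rs110413607	10	34156200	RASGRP1	in	-0.44	2	0.177	0.595	1	-0.259	0.405	48.43
rs109718130	10	34176744	RASGRP1	in	-0.43	2	0.149	0.655	1	-0.283	0.345	44.37
rs110493658	10	34336811	RASGRP1	d	0.43	1	0.179	0.588	2	-0.256	0.412	48.84
rs136476033	10	34624568	LOC104973119-LOC104973122	between	0.40	1	0.144	0.643	2	-0.260	0.357	40.04
rs134389993	10	35187157	THBS1	u	-0.42	2	0.200	0.521	1	-0.218	0.479	46.25
rs137782429	10	35924151	PLCB2	in	0.44	1	0.160	0.636	2	-0.279	0.364	47.14
rs110524929	11	78663074	SDC1-LAPTM4A	between	0.41	1	0.268	0.343	2	-0.140	0.657	40.47
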