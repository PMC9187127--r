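Region	SNP	Population	Sex	CallRate	RR	RA	AA	MinorAllele	sdMAF	sdMAF.p	HWD.delta	HWE.p
PAR1	X-2779827-G-A	NFE	F	99.72	19436	194	1	A	NA	NA	0.000	0.46
PAR1	X-2779827-G-A	NFE	M	99.50	626	13577	67	A	-0.475	<1E-300	-0.226	<1E-300
PAR1	X-2779827-G-A	AFR	F	99.16	6772	3707	514	A	NA	NA	0.000	0.82
PAR1	X-2779827-G-A	AFR	M	99.08	248	7346	1975	A	-0.375	<1E-300	-0.142	<1E-300
PAR1	X-2780882-G-A	NFE	F	99.85	19567	89	0	A	NA	NA	0.000	0.75
PAR1	X-2780882-G-A	NFE	M	99.64	91	14150	39	A	-0.496	<1E-300	-0.245	<1E-300
PAR1	X-2780882-G-A	AFR	F	99.51	8781	2118	133	A	NA	NA	0.000	0.68
PAR1	X-2780882-G-A	AFR	M	99.64	137	8442	1044	A	-0.439	<1E-300	-0.191	<1E-300
NPR	X-52861869-T-C	NFE	F	98.54	14176	5222	1	C	NA	NA	-0.018	1.45E-103
NPR	X-52861869-T-C	NFE	M	85.50	12189	NA	73	C	0.129	<1E-300	NA	NA
NPR	X-52861869-T-C	AFR	F	99.36	9642	1368	5	C	NA	NA	-0.003	6.00E-10
NPR	X-52861869-T-C	AFR	M	90.36	8552	NA	175	C	0.042	1.43E-84	NA	NA
PAR3	X-89688092-A-G	NFE	F	99.48	13994	5106	483	G	NA	NA	0.001	0.50
PAR3	X-89688092-A-G	NFE	M	89.78	11538	NA	1338	G	0.051	1.37E-55	NA	NA
PAR3	X-89688092-A-G	AFR	F	99.56	9694	1300	43	G	NA	NA	0.000	0.93
PAR3	X-89688092-A-G	AFR	M	84.52	7865	NA	298	G	0.026	2.44E-23	NA	NA
PAR3	X-90958827-T-C	NFE	F	99.38	15016	4218	330	C	NA	NA	0.001	0.09
PAR3	X-90958827-T-C	NFE	M	91.08	12039	NA	1025	C	0.046	1.66E-57	NA	NA
PAR3	X-90958827-T-C	AFR	F	99.31	9611	1353	45	C	NA	NA	0.000	0.72
PAR3	X-90958827-T-C	AFR	M	85.60	7990	NA	277	C	0.032	3.17E-35	NA	NA
NPR	X-141051591-A-G	NFE	F	99.31	14846	4700	5	G	NA	NA	-0.014	6.07E-79
NPR	X-141051591-A-G	NFE	M	79.08	11253	NA	89	G	0.113	<1E-300	NA	NA
NPR	X-141051591-A-G	AFR	F	98.57	8826	2095	7	G	NA	NA	-0.009	2.57E-25
NPR	X-141051591-A-G	AFR	M	84.68	8057	NA	121	G	0.082	<1E-300	NA	NA
PAR2	X-155706522-G-A	NFE	F	98.23	19321	16	0	A	NA	NA	0.000	0.95
PAR2	X-155706522-G-A	NFE	M	97.92	30	14012	2	A	-0.499	<1E-300	-0.249	<1E-300
PAR2	X-155706522-G-A	AFR	F	98.71	10933	10	0	A	NA	NA	0.000	0.96
PAR2	X-155706522-G-A	AFR	M	99.26	11	9573	3	A	-0.499	<1E-300	-0.249	<1E-300
PAR2	X-155712209-T-G	NFE	F	99.63	19585	28	0	G	NA	NA	0.000	0.92
PAR2	X-155712209-T-G	NFE	M	99.12	29	14186	2	G	-0.498	<1E-300	-0.249	<1E-300
PAR2	X-155712209-T-G	AFR	F	99.58	10520	516	3	G	NA	NA	0.000	0.19
PAR2	X-155712209-T-G	AFR	M	99.78	14	9404	218	G	-0.487	<1E-300	-0.238	<1E-300
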