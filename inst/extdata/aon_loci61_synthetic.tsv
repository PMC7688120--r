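snp_id	chrom	pos	focal_allele	other_allele	HR1	HR2	HR3	HR4	C1	C2	C3	C4
syn009	chr1	40000000	T	G	1	1	1	1	0.35	0.27	0.73	0.74
syn010	chr1	41100000	C	T	1	1	1	1	0.71	0.57	0.41	0.72
syn011	chr1	41700000	G	C	1	1	1	1	0.86	0.27	0.31	0.21
syn037	chr11	60000000	A	T	0.19	0.32	0.88	0.69	1	1	1	1
syn038	chr11	61000000	C	A	0.25	0.43	0.52	0.71	1	1	1	1
syn039	chr11	62200000	T	A	0.26	0.88	0.5	0.11	1	1	1	1
syn040	chr11	62500000	G	C	0.37	0.36	0.3	0.62	1	1	1	1
syn041	chr13	33000000	T	G	1	1	1	1	0.46	0.38	0.3	0.16
syn042	chr13	34200000	G	C	1	1	1	1	0.89	0.8	0.11	0.23
syn043	chr13	34850000	G	T	1	1	1	1	0.14	0.25	0.4	0.41
syn044	chr13	35250000	T	C	1	1	1	1	0.65	0.77	0	0.42
syn045	chr13	35400000	C	G	1	1	1	1	0.7	0.13	0.7	0.52
syn046	chr13	36450000	A	C	1	1	1	1	0.87	0.86	0.53	0.53
syn047	chr13	36950000	A	C	1	1	1	1	0.74	0.29	0.8	0.54
syn048	chr15	80000000	T	A	1	1	1	1	0.75	0.52	0.81	0.32
syn049	chr15	80700000	A	G	1	1	1	1	0.87	0.45	0.36	0.16
syn050	chr15	81350000	A	G	1	1	1	1	0.85	0.52	0.62	0.13
syn051	chr15	82400000	G	T	1	1	1	1	0.19	0.85	0.16	0.44
syn052	chr15	83450000	T	A	1	1	1	1	0.52	0.52	0.82	0.64
syn053	chr15	84500000	G	T	1	1	1	1	0.14	0.39	0.81	0.37
syn054	chr15	85300000	C	A	1	1	1	1	0.55	0.64	0.4	0.55
syn055	chr15	86450000	C	T	1	1	1	1	0.13	0.33	0.29	0.51
syn056	chr15	86700000	T	A	1	1	1	1	0.83	0.46	0.31	0.68
rs29503987	chr17	18001459	C	A	1	1	1	1	0.85	0.72	0.63	0.69
rs33375308	chr17	18210739	T	C	1	1	1	1	0.6	0.14	0.66	0.24
rs33447983	chr17	19403011	G	T	1	1	1	1	0.15	0.39	0.25	0.24
rs6224641	chr17	19424358	A	G	1	1	1	1	0.25	0.59	0.24	0.7
rs33649277	chr17	19616228	G	A	1	1	1	1	0.78	0.3	0.38	0.85
rs29522462	chr17	20573305	A	C	1	1	1	1	0.63	0.67	0.75	0.86
rs33120398	chr17	20587484	C	T	1	1	1	1	0.89	0.26	0.13	0.17
rs33463529	chr17	20779567	G	A	1	1	1	1	0.53	0.6	0.61	0.45
syn057	chr19	25000000	C	G	0.67	0.63	0.41	0.23	1	1	1	1
syn058	chr19	25950000	C	G	0.11	0.89	0.24	0.65	1	1	1	1
syn059	chr19	27000000	T	C	0.71	0.81	0.16	0.26	1	1	1	1
syn012	chr2	72000000	C	A	0	0.13	0.26	0.73	1	1	1	1
syn013	chr2	72150000	C	A	0.81	0.12	0.12	0.52	1	1	1	1
syn014	chr2	73050000	A	G	0.45	0.34	0.6	0.44	1	1	1	1
syn015	chr2	73950000	T	G	0.16	0.34	0.31	0.87	1	1	1	1
syn060	chr3	50123456	A	G	1	1	1	1	0.24	0.7	0.45	0.34
syn016	chr4	55000000	A	G	1	1	1	1	0.66	0.3	0.74	0.58
syn017	chr4	55450000	T	G	1	1	1	1	0.81	0.35	0.51	0.84
syn018	chr4	55650000	T	C	1	1	1	1	0.79	0.62	0.44	0.33
syn019	chr4	56150000	T	G	1	1	1	1	0.7	0.28	0.38	0.87
syn020	chr4	57250000	A	G	1	1	1	1	0.57	0.29	0.58	0.42
syn021	chr5	120000000	A	G	1	1	1	1	0.18	0.8	0.59	0.39
syn022	chr5	120700000	T	A	1	1	1	1	0.78	0.15	0.12	0.7
syn023	chr5	121300000	T	G	1	1	1	1	0.83	0.29	0.45	0.41
syn024	chr7	18000000	A	G	0.87	0.53	0.71	0.76	1	1	1	1
syn025	chr7	18400000	C	A	0.39	0.76	0.17	0.77	1	1	1	1
syn026	chr7	19250000	A	C	0.74	0.49	0.27	0.32	1	1	1	1
syn027	chr7	20200000	C	T	0.88	0	0.76	0.39	1	1	1	1
syn028	chr7	21150000	T	A	0.42	0.54	0.51	0.32	1	1	1	1
syn029	chr7	21300000	A	G	0.58	0.69	0.24	0.65	1	1	1	1
syn061	chr8	91234567	T	C	0.8	0.68	0.5	0.75	1	1	1	1
syn030	chr9	95000000	A	G	1	1	1	1	0.2	0.72	0.49	0.42
syn031	chr9	95800000	G	C	1	1	1	1	0.35	0.71	0.42	0.21
syn032	chr9	96600000	C	G	1	1	1	1	0.28	0.67	0.14	0.71
syn033	chr9	96800000	T	A	1	1	1	1	0.79	0.55	0.38	0.23
syn034	chr9	96950000	T	C	1	1	1	1	0.48	0.11	0.39	0.86
syn035	chr9	97150000	A	T	1	1	1	1	0.52	0.74	0.88	0.85
syn036	chr9	98000000	C	A	1	1	1	1	0.34	0.77	0.54	0.31
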