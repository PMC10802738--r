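# Transcribed published summary statistics: the 17 serum proteins whose incident-LOAD
# association is APOE-e4-dependent (Cox PH model 1 = age+sex; model 2 adds e4 allele count;
# linear-regression effect of e4 dose on protein level). Reported values, not computed here.
aptamer	symbol	hr_model1	fdr_model1	hr_model2	p_model2	beta_e4	se_e4	p_e4	fdr_e4
11293_14_3	LRRN1	1.258	1e-05	1.018	0.711	1.061	0.023	1e-300	1e-300
7223_60_3	S100A13	0.799	7e-05	1.099	0.092	-1.090	0.021	1e-300	1e-300
12501_10_3	TBCA	0.782	7e-06	1.086	0.145	-1.183	0.020	1e-300	1e-300
13732_79_3	CTF1	1.262	2e-04	1.077	0.147	0.611	0.021	1e-171	5e-171
12587_65_3	ARL2	0.835	0.002	1.093	0.077	-0.991	0.022	1e-300	1e-300
5744_12_3	C1orf56	1.200	0.002	1.070	0.113	0.513	0.026	6e-85	9e-85
5009_11_1	MSN	1.186	0.003	1.039	0.388	0.608	0.025	9e-122	2e-121
8922_4_3	TMCC3	0.849	0.005	0.962	0.364	-0.517	0.026	4e-86	7e-86
7965_25_3	HBQ1	0.860	0.013	0.966	0.423	-0.455	0.025	1e-69	1e-69
9999_1_3	IRF6	0.876	0.032	1.033	0.458	-0.675	0.025	4e-153	1e-152
9853_3_3	IFIT2	0.875	0.035	0.949	0.214	-0.275	0.026	2e-26	2e-26
13022_20_3	TP53I11	0.879	0.036	0.981	0.653	-0.436	0.026	1e-60	1e-60
10635_33_3	FAM159B	0.882	0.039	0.977	0.591	-0.419	0.026	8e-56	9e-56
9765_4_3	NDE1	0.876	0.039	1.001	0.985	-0.489	0.025	3e-80	5e-80
10082_251_3	NEFL	0.878	0.041	1.031	0.516	-0.578	0.024	2e-121	4e-121
7239_9_3	GSTM1	1.136	0.042	1.077	0.087	0.276	0.026	1e-26	1e-26
6334_9_3	GGT2	0.887	0.048	0.981	0.646	-0.384	0.026	2e-47	3e-47
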