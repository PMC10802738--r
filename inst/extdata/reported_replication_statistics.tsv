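# Transcribed published summary statistics: replication of incident-LOAD protein
# associations in an external clinical (MCI-to-LOAD conversion) cohort, Cox PH models 1
# (age+sex) and 2 (+e4). All proteins with nominal P < 0.05 in either model. The group
# column records the APOE-dependence label assigned in the discovery cohort.
aptamer	symbol	group	hr_m1	p_m1	fdr_m1	hr_m2	p_m2	fdr_m2
11293_14_3	LRRN1	Dependent	1.410	5.4e-09	1.8e-06	1.142	0.112	0.839
5744_12_3	C1orf56	Dependent	1.354	4.3e-06	5.2e-04	1.175	0.024	0.565
13732_79_3	CTF1	Dependent	1.324	4.7e-06	5.2e-04	1.034	0.666	0.958
10082_251_3	NEFL	Dependent	0.771	2.5e-05	0.002	1.084	0.346	0.958
12501_10_3	TBCA	Dependent	0.789	2.3e-04	0.015	1.279	0.009	0.336
6462_12_3	TIMP4	Independent	1.261	4.0e-04	0.022	1.236	1.2e-03	0.198
8819_3_3	IGFBP2	Independent	1.253	0.002	0.085	1.250	0.002	0.204
2570_72_5	IGFBP2	Independent	1.237	0.002	0.085	1.234	0.002	0.204
8469_41_3	IGFBP2	Independent	1.230	0.004	0.164	1.222	0.006	0.316
10978_39_3	GH2	Independent	1.182	0.009	0.298	1.131	0.053	0.751
2813_11_2	AGRP	Other	1.187	0.011	0.346	1.196	0.008	0.323
7100_31_3	CD2	Independent	1.166	0.014	0.353	1.102	0.121	0.839
6168_11_3	TP53	Other	1.190	0.015	0.353	1.127	0.104	0.839
4964_67_1	ERAP1	Independent	0.861	0.015	0.353	0.841	0.007	0.316
7223_60_3	S100A13	Dependent	0.853	0.016	0.353	1.500	3.1e-05	0.010
4930_21_1	STC1	Independent	1.173	0.021	0.391	1.174	0.021	0.565
9539_25_3	COL26A1	Other	0.865	0.022	0.391	0.890	0.059	0.756
7239_9_3	GSTM1	Dependent	1.159	0.023	0.391	1.070	0.304	0.951
4929_55_1	SHBG	Other	1.168	0.023	0.391	1.149	0.042	0.751
13118_5_3	SMOC1	Independent	1.172	0.024	0.391	1.157	0.041	0.751
5660_51_3	SOD3	Independent	1.162	0.026	0.411	1.162	0.026	0.565
5581_28_3	FGL1	Other	1.149	0.028	0.430	1.118	0.077	0.757
13022_20_3	TP53I11	Dependent	0.877	0.035	0.458	1.059	0.388	0.958
8235_48_3	CHGB	Other	1.151	0.035	0.458	1.123	0.088	0.797
7016_12_3	GCNT1	Independent	0.864	0.036	0.458	0.874	0.052	0.751
13731_14_3	C7	Independent	1.159	0.036	0.458	1.147	0.049	0.751
2925_9_1	SERPINE1	Other	0.875	0.042	0.511	0.870	0.038	0.751
3290_50_2	CD109	Independent	0.884	0.043	0.511	0.896	0.076	0.757
6626_81_3	CHST12	Independent	0.871	0.045	0.518	0.904	0.146	0.848
6604_59_3	NDNF	Other	0.879	0.048	0.528	0.897	0.096	0.817
14129_1_3	IFNA7	Other	1.131	0.051	0.543	1.134	0.045	0.751
8072_19_3	MZT1	Independent	1.118	0.058	0.604	1.146	0.022	0.565
4982_54_1	PI3	Other	1.139	0.070	0.608	1.185	0.020	0.565
4297_62_3	SPON1	Independent	1.127	0.073	0.608	1.167	0.025	0.565
8242_9_3	CLEC2L	Independent	1.102	0.124	0.686	1.136	0.045	0.751
12587_65_3	ARL2	Dependent	0.909	0.130	0.686	1.252	0.004	0.255
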