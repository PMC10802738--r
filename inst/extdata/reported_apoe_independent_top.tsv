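# Transcribed published summary statistics: top 20 APOE-independent serum proteins
# associated with incident LOAD (Cox PH model 2: age + sex + e4 allele count; hazard
# ratio per SD of protein). APOE-independence = FDR < 0.05 after e4 adjustment.
aptamer	symbol	hr_model2	p_model2	fdr_model2
3143_3_1	CD4	0.79	1.9e-07	9.3e-04
10043_31_3	BRD4	0.82	1.4e-06	3.4e-03
5496_49_3	SPON1	1.24	3.6e-06	3.9e-03
8242_9_3	CLEC2L	0.83	5.7e-06	3.9e-03
8463_2_3	SOD3	1.21	5.2e-06	3.9e-03
10980_11_3	ACHE	1.22	3.9e-06	3.9e-03
2991_9_2	IL1R1	1.23	4.7e-06	3.9e-03
8520_8_3	ADAM30	0.83	1.1e-05	6.0e-03
2447_7_4	PLA2G2E	0.82	1.2e-05	6.0e-03
3336_50_1	TFPI	1.20	1.3e-05	6.0e-03
11178_21_3	SVEP1	1.21	2.5e-05	0.011
11109_56_3	SVEP1	1.21	3.3e-05	0.011
4304_18_2	LCORL	0.82	3.2e-05	0.011
2247_20_11	PROK1	0.84	3.1e-05	0.011
4498_62_2	NCAM1	1.20	4.0e-05	0.011
13118_5_3	SMOC1	1.21	3.9e-05	0.011
5660_51_3	SOD3	1.19	4.0e-05	0.011
8052_115_3	NLGN1	1.18	4.5e-05	0.011
8009_121_3	SURF1	1.19	4.3e-05	0.011
6973_2_3	IGF2	0.84	5.4e-05	0.012
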