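ID	GeneID	chr	strand	exonStart_0base	exonEnd	upstreamEE	downstreamES	IJC_SAMPLE_1	SJC_SAMPLE_1	IJC_SAMPLE_2	SJC_SAMPLE_2	IncLevel1	IncLevel2	PValue	FDR	IncLevelDifference
E1	GENE_A	chrT	+	1000	1100	700	1400	6,5	2,3	2,2	3,3	0.8,0.7	0.45,0.45	0.001	0.01	0.3
E2	GENE_B	chrT	+	2000	2100	1700	2400	3,2	2,1	2,1	2,1	0.6,0.6	0.3,0.3	0.002	0.01	0.3
E3	GENE_C	chrT	-	3000	3100	2700	3400	10,10	5,5	10,10	5,5	0.7,0.7	0.6,0.6	0.003	0.01	0.1
E4	GENE_D	chrT	+	4000	4100	3700	4400	8,8	2,2	4,4	6,6	0.8,0.8	0.4,0.4	0.02	0.05	0.4
E5	GENE_E	chrT	-	5000	5100	4700	5400	20,15	15,10	5,3	1,1	0.55,0.6	0.8,0.85	0.001	0.001	-0.25
E6	GENE_F	chrT	+	6000	6100	5700	6400	5,4	6,5	12,13	15,15	0.45,0.44	0.44,0.46	0.8	0.9	-0.005
E7	GENE_G	chrT	+	7000	7100	6700	7400	1,1	19,19	1,1	19,19	0.05,0.05	0.05,0.05	0.85	0.9	0
E8	GENE_H	chrT	-	8000	8100	7700	8400	3,2	1,2	2,2	2,1	0.62,0.62	0.5,0.5	0.03	0.049	0.12
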