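metabolite	median_umol_per_L	intra_assay_cv_pct	intra_individual_cv_pct	inter_individual_cv_pct
creatinine	10000	1.00	40.00	60.00
creatine	300	4.12	126.19	239.55
alanine	250	1.16	28.69	49.88
glycine	1000	2.21	34.71	73.98
histidine	400	1.10	30.25	48.81
threonine	130	4.57	38.58	75.44
valine	40	4.72	20.28	39.50
isoleucine	15	6.68	23.27	54.06
tyrosine	100	3.35	32.09	45.76
glucose	300	2.91	13.76	1654.62
lactate	150	4.28	44.26	476.52
citrate	2500	1.51	27.92	53.35
hippurate	2000	1.15	58.45	69.26
formate	250	8.71	41.32	584.66
dimethylamine	300	0.74	9.79	30.48
trimethylamine-N-oxide	400	1.63	80.89	127.14
2-hydroxyisobutyrate	80	1.15	16.25	35.39
3-hydroxyisovalerate	100	4.84	66.55	46.16
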