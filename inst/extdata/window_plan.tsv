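window_id	high_ppm	low_ppm	metabolites	report
w_formate	8.60	8.30	formate	formate
w_aromatic	8.00	7.60	hippurate,histidine	hippurate,histidine
w_tyrosine	7.35	6.75	tyrosine	tyrosine
w_glucose	5.40	5.05	glucose	glucose
w_glycine	3.65	3.35	glycine,glucose	glycine
w_tmao	3.35	3.18	trimethylamine-N-oxide	trimethylamine-N-oxide
w_creatinine	3.14	2.96	creatinine,creatine	creatinine,creatine
w_citrate	2.85	2.40	citrate,dimethylamine	citrate,dimethylamine
w_aliphatic	1.60	1.15	alanine,2-hydroxyisobutyrate,lactate,threonine,3-hydroxyisovalerate	alanine,2-hydroxyisobutyrate,lactate,threonine,3-hydroxyisovalerate
w_bcaa	1.12	0.85	valine,isoleucine	valine,isoleucine
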