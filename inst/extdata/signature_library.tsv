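metabolite	pathway	group	center_ppm	n_protons	couplings	mobility_ppm
creatinine	muscle metabolism	CH3	3.050	3		0.003
creatinine	muscle metabolism	CH2	4.060	2		0.004
creatine	glycine, serine and threonine metabolism	CH3	3.040	3		0.002
creatine	glycine, serine and threonine metabolism	CH2	3.930	2		0.004
alanine	amino acids	CH3	1.480	3	7.2:1	0.003
alanine	amino acids	CH	3.780	1	7.2:3	0.005
glycine	amino acids	CH2	3.560	2		0.003
histidine	amino acids	ring-H2	7.800	1		0.020
threonine	amino acids	CH3	1.320	3	6.6:1	0.003
valine	branched-chain amino acids	CH3-a	1.040	3	7.0:1	0.003
valine	branched-chain amino acids	CH3-b	0.990	3	7.0:1	0.003
isoleucine	branched-chain amino acids	CH3-d	1.010	3	7.0:1	0.003
isoleucine	branched-chain amino acids	CH3-t	0.940	3	7.4:2	0.003
tyrosine	aromatic amino acids	ring-2,6	7.190	2	8.5:1	0.008
tyrosine	aromatic amino acids	ring-3,5	6.900	2	8.5:1	0.008
glucose	glycolysis-related metabolites	H1-alpha	5.230	1	3.8:1	0.003
glucose	glycolysis-related metabolites	ring	3.410	2	9.6:1	0.005
lactate	glycolysis-related metabolites	CH3	1.330	3	6.9:1	0.003
lactate	glycolysis-related metabolites	CH	4.110	1	6.9:3	0.004
citrate	citrate cycle-related metabolites	AB-low	2.540	2	15.4:1	0.008
citrate	citrate cycle-related metabolites	AB-high	2.660	2	15.4:1	0.008
hippurate	phenylalanine metabolism	ring-ortho	7.830	2	7.7:1	0.004
hippurate	phenylalanine metabolism	CH2	3.970	2	5.9:1	0.004
formate	microbial metabolism	CH	8.460	1		0.010
dimethylamine	microbial metabolism	CH3	2.720	6		0.003
trimethylamine-N-oxide	microbial metabolism	CH3	3.270	9		0.005
2-hydroxyisobutyrate	miscellaneous	CH3	1.360	6		0.003
3-hydroxyisovalerate	miscellaneous	CH3	1.270	6		0.003
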