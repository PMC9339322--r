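clade	phylum	ml_bm	ml_ou	ml_levy	p_levy_vs_bm	n_taxa	ancestral_gc	n_jumps	n_down	n_up
Cytophagales	Bacteroidetes	-445.252	-445.252	-426.24	5.5e-09	167	40.07	2	1	1
Bacteroidales	Bacteroidetes	-1886.49	-1886.49	-1831.52	1e-16	713	40.1	3	0	3
Flavobacteriales	Bacteroidetes	-1364.19	-1364.19	-1204.14	1e-16	609	39.89	73	19	54
Acetobacterales_and_related	Proteobacteria_alpha	-572.371	-572.371	-537.383	6.7e-16	198	62.84	7	6	1
Sphingomonadales	Proteobacteria_alpha	-540.688	-540.688	-471.786	1e-16	260	55.84	11	9	2
Rhizobiales	Proteobacteria_alpha	-1040.84	-1040.84	-863.626	1e-16	538	63.8	23	17	6
Rhodobacterales	Proteobacteria_alpha	-1141.83	-1141.83	-1033.02	1e-16	469	63.38	27	20	7
Betaproteobacteriales	Proteobacteria_gamma	-1859.95	-1859.949	-1690.86	1e-16	770	58.12	24	20	4
Enterobacterales	Proteobacteria_gamma	-1441.81	-1440.58	-1314.91	1e-16	602	45.99	18	7	11
Pseudomonadales	Proteobacteria_gamma	-1485.58	-1485.572	-1406.66	1e-16	632	52.02	13	11	2
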