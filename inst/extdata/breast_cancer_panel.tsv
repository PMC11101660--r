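disease_id	gene_id	carrier_prevalence	penetrance	precision	test_disutility
female_breast_cancer	ATM	0.0019	0.35	100	0
female_breast_cancer	BRCA1	0.00058	0.73	10000	0
female_breast_cancer	BRCA2	0.00068	0.72	10000	0
female_breast_cancer	CHEK2	0.0026	0.19	100	0
female_breast_cancer	PALB2	0.00057	0.38	100	0
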