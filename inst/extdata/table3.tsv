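cohort_id	group	phenotype_desc	n_total	n_hap_possible	n_informative	n_cis_in_trans
this_study	MISSING_HERITABILITY	Nystagmus and/or albinism	51	49	23	23
oetting	MISSING_HERITABILITY	OCA1	3	2	2	2
ghodsinejad	MISSING_HERITABILITY	OCA1	6	0	0	0
lasseaux	MISSING_HERITABILITY	Nystagmus and/or absence of fovea	158	64	31	31
gronskov	MISSING_HERITABILITY	Albinism (OCA, AROA or OA)	29	21	6	6
campbell	MISSING_HERITABILITY	Nystagmus plus ocular albinism features	4	4	2	2
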