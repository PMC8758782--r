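cohort_id	group	phenotype_desc	n_total	n_hap_possible
this_study	MISSING_HERITABILITY	Nystagmus and/or albinism	51	49
hutton_spritz_2008a	MISSING_HERITABILITY	AROA / mild OCA	20	1
hutton_spritz_2008b	MISSING_HERITABILITY	OCA	13	3
oetting	MISSING_HERITABILITY	OCA1	3	2
ghodsinejad	MISSING_HERITABILITY	OCA1	6	0
lasseaux	MISSING_HERITABILITY	Nystagmus and/or absence of fovea	158	64
gronskov	MISSING_HERITABILITY	Albinism (OCA, AROA or OA)	29	21
campbell	MISSING_HERITABILITY	Nystagmus plus ocular albinism features	4	4
this_study_dx	MOLECULARLY_DIAGNOSED	Nystagmus and/or albinism	71	2
hutton_spritz_2008b_dx	MOLECULARLY_DIAGNOSED	OCA	9	0
oetting_dx	MOLECULARLY_DIAGNOSED	OCA1	19	0
gronskov_dx	MOLECULARLY_DIAGNOSED	Albinism (OCA, AROA or OA)	2	0
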