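# Published cohort table: 1000 Genomes Project phase 3 populations plus
# HGDP Native American reference populations, with continental group and
# the number of genomes analyzed per population.
group	population	description	n
African	MSL	Mende in Sierra Leone	85
African	YRI	Yoruba in Ibadan, Nigeria	108
East Asian	CDX	Chinese Dai in Xishuangbanna, China	93
East Asian	CHB	Han Chinese in Bejing, China	103
East Asian	CHS	Southern Han Chinese, China	105
East Asian	JPT	Japanese in Tokyo, Japan	104
East Asian	KHV	Kinh in Ho Chi Minh City, Vietnam	99
European	CEU	Utah residents with NW European ancestry	99
European	IBS	Iberian populations in Spain	107
European	GBR	British in England and Scotland	91
Admixed American	CLM	Colombian in Medellin, Colombia	94
Admixed American	MXL	Mexican Ancestry in Los Angeles, California	64
Admixed American	PEL	Peruvian in Lima, Peru	85
Admixed American	PUR	Puerto Rican in Puerto Rico	104
Native American	KRT	Karitiana in Brazil	24
Native American	SRI	Surui in Brazil	21
Native American	COL	Colombians in Colombia	13
Native American	MAY	Maya in Mexico	25
Native American	PIM	Pima in Mexico	25
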