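variant_id	position	wt_aa	mut_aa	disease_category	in_panel	is_null_allele	assayed	retinol_pct	retinol_sem	steroid_pct	steroid_sem	stability_class	zygosity	partner	partner_assayed	reported_phenotype	printed_retinol	printed_steroid	printed_verdict	verdict_override	note
P52L	52	P	L	BOTH	TRUE	FALSE	TRUE	0.00	0.00	70.97	4.36	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	PCG	50	85	NO	FALSE	
P52L	52	P	L	BOTH	TRUE	FALSE	TRUE	0.00	0.00	70.97	4.36	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	JOAG	50	85	NO	FALSE	
W57C	57	W	C	BOTH	TRUE	FALSE	TRUE	221.71	16.19	337.84	20.38	UNSTABLE	HOMOZYGOUS	W57C	TRUE	PCG	221	338	YES	FALSE	
W57C	57	W	C	BOTH	TRUE	FALSE	TRUE	221.71	16.19	337.84	20.38	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	JOAG	161	219	YES	FALSE	
G61E	61	G	E	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	HOMOZYGOUS	G61E	TRUE	PCG	0	0	YES	FALSE	
G61E	61	G	E	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	HOMOZYGOUS	G61E	TRUE	JOAG	0	0	YES	FALSE	yes for homozygote if escaped PCG due to incomplete penetrance
G61E	61	G	E	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	50	50	YES	FALSE	
G61E	61	G	E	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	COMPOUND_HET	R355fsX69	FALSE	PCG	0	0	YES	FALSE	
G61E	61	G	E	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	COMPOUND_HET	Y81N	TRUE	POAG	0	5	YES	FALSE	
R117W	117	R	W	PCG_ONLY	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	COMPOUND_HET	R469W	TRUE	PCG	62	3	NO	FALSE	
R117P	117	R	P	PCG_ONLY	TRUE	FALSE	TRUE	0.00	0.00	70.63	2.60	UNSTABLE	COMPOUND_HET	R390H	FALSE	PCG	NA	NA	INCONCLUSIVE	FALSE	biochemical assay not done for R390H
M132R	132	M	R	PCG_ONLY	TRUE	FALSE	TRUE	0.00	0.00	35.35	2.03	STABLE	HOMOZYGOUS	M132R	TRUE	PCG	0	36	YES	FALSE	
E229K	229	E	K	BOTH	TRUE	FALSE	TRUE	137.28	6.51	167.65	34.37	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	PCG	119	134	NA	FALSE	verdict not furnished for the PCG heterozygote
E229K	229	E	K	BOTH	TRUE	FALSE	TRUE	137.28	6.51	167.65	34.37	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	119	134	INCONCLUSIVE	TRUE	printed inconclusive despite determinate inferred activity
E229K	229	E	K	BOTH	TRUE	FALSE	TRUE	137.28	6.51	167.65	34.37	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	JOAG	119	134	NO	TRUE	printed no despite steroid excess under default thresholds
E229K	229	E	K	BOTH	TRUE	FALSE	TRUE	137.28	6.51	167.65	34.37	STABLE	COMPOUND_HET	P193L	FALSE	PCG	NA	NA	INCONCLUSIVE	FALSE	biochemical assay not done for P193L
E229K	229	E	K	BOTH	TRUE	FALSE	TRUE	137.28	6.51	167.65	34.37	STABLE	COMPOUND_HET	c.1064-1076del	FALSE	PCG	69	84	NO	FALSE	
F261L	261	F	L	PCG_ONLY	TRUE	FALSE	TRUE	243.15	15.48	22.22	1.86	STABLE	COMPOUND_HET	R355fsX69	FALSE	PCG	122	11	YES	FALSE	
D291G	291	D	G	PCG_ONLY	TRUE	FALSE	TRUE	0.00	0.00	41.12	18.19	UNSTABLE	HOMOZYGOUS	D291G	TRUE	PCG	0	42	YES	FALSE	
G329S	329	G	S	PCG_ONLY	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	STABLE	COMPOUND_HET	T325SfsX104	FALSE	PCG	0	0	YES	FALSE	
R368H	368	R	H	BOTH	TRUE	FALSE	TRUE	0.00	0.00	21.29	2.40	STABLE	HOMOZYGOUS	R368H	TRUE	PCG	0	22	YES	FALSE	
R368H	368	R	H	BOTH	TRUE	FALSE	TRUE	0.00	0.00	21.29	2.40	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	50	61	NA	FALSE	verdict not furnished for the POAG heterozygote
R368H	368	R	H	BOTH	TRUE	FALSE	TRUE	0.00	0.00	21.29	2.40	STABLE	COMPOUND_HET	M292K	TRUE	POAG	90	11	YES	FALSE	
R368H	368	R	H	BOTH	TRUE	FALSE	TRUE	0.00	0.00	21.29	2.40	STABLE	COMPOUND_HET	1546dup10	FALSE	JOAG	0	11	YES	FALSE	likely if accompanied by MYOC mutation
E387K	387	E	K	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	HOMOZYGOUS	E387K	TRUE	PCG	0	0	YES	FALSE	
E387K	387	E	K	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	COMPOUND_HET	8182delG	FALSE	PCG	0	0	YES	FALSE	
E387K	387	E	K	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	COMPOUND_HET	P437L	FALSE	PCG	NA	NA	INCONCLUSIVE	FALSE	biochemical assay not done for P437L
E387K	387	E	K	BOTH	TRUE	FALSE	TRUE	0.00	0.00	0.00	0.00	UNSTABLE	COMPOUND_HET	G232R	FALSE	JOAG	NA	NA	INCONCLUSIVE	FALSE	biochemical assay not done for G232R
R444Q	444	R	Q	PCG_ONLY	TRUE	FALSE	TRUE	274.15	5.80	25.71	2.65	UNSTABLE	HOMOZYGOUS	R444Q	TRUE	PCG	274	26	YES	FALSE	
R444Q	444	R	Q	PCG_ONLY	TRUE	FALSE	TRUE	274.15	5.80	25.71	2.65	UNSTABLE	COMPOUND_HET	3964delC	FALSE	PCG	137	13	YES	FALSE	
R469W	469	R	W	PCG_ONLY	TRUE	FALSE	TRUE	124.20	25.30	5.79	1.04	STABLE	HOMOZYGOUS	R469W	TRUE	PCG	124	6	YES	FALSE	
S28W	28	S	W	POAG_ONLY	TRUE	FALSE	TRUE	0.00	0.00	600.41	28.58	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	50	350	YES	FALSE	
Y81N	81	Y	N	BOTH	TRUE	FALSE	TRUE	0.00	0.00	10.41	5.50	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	PCG	50	55	NO	FALSE	
Y81N	81	Y	N	BOTH	TRUE	FALSE	TRUE	0.00	0.00	10.41	5.50	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	50	55	YES	FALSE	
Y81N	81	Y	N	BOTH	TRUE	FALSE	TRUE	0.00	0.00	10.41	5.50	UNSTABLE	COMPOUND_HET	G61E	TRUE	POAG	0	5	YES	FALSE	
Y81N	81	Y	N	BOTH	TRUE	FALSE	TRUE	0.00	0.00	10.41	5.50	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	JOAG	50	55	YES	FALSE	yes if accompanied by MYOC mutation
Q144H	144	Q	H	POAG_ONLY	TRUE	FALSE	TRUE	82.67	6.36	14.99	2.08	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	91	57	YES	FALSE	
Q144R	144	Q	R	BOTH	TRUE	FALSE	TRUE	0.00	0.00	84.80	1.45	STABLE	NOT_AVAILABLE	NA	NA	PCG	0	85	PREDICTED	FALSE	predicted for a homozygote
Q144R	144	Q	R	BOTH	TRUE	FALSE	TRUE	0.00	0.00	84.80	1.45	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	50	92	NO	FALSE	
M292K	292	M	K	POAG_ONLY	TRUE	FALSE	TRUE	181.50	6.84	0.00	0.00	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	141	50	YES	FALSE	
M292K	292	M	K	POAG_ONLY	TRUE	FALSE	TRUE	181.50	6.84	0.00	0.00	STABLE	COMPOUND_HET	R368H	TRUE	POAG	90	11	YES	FALSE	
V409F	409	V	F	POAG_ONLY	TRUE	FALSE	TRUE	71.50	12.55	151.49	2.96	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	86	126	INCONCLUSIVE	TRUE	printed inconclusive despite determinate inferred activity
F445C	445	F	C	BOTH	TRUE	FALSE	TRUE	226.67	14.53	55.03	1.73	STABLE	NOT_AVAILABLE	NA	NA	PCG	227	55	PREDICTED	FALSE	predicted for a homozygote
F445C	445	F	C	BOTH	TRUE	FALSE	TRUE	226.67	14.53	55.03	1.73	STABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	164	78	INCONCLUSIVE	TRUE	printed inconclusive despite determinate inferred activity
R523T	523	R	T	POAG_ONLY	TRUE	FALSE	TRUE	210.85	9.93	8.21	7.62	UNSTABLE	HOMOZYGOUS	R523T	TRUE	JOAG	211	8	YES	FALSE	potentially incomplete penetrance of PCG
D530G	530	D	G	POAG_ONLY	TRUE	FALSE	TRUE	0.00	0.00	88.19	2.60	UNSTABLE	HETEROZYGOUS	WILD_TYPE	TRUE	POAG	50	94	NO	FALSE	
R355fsX69	NA	NA	NA	NA	FALSE	TRUE	FALSE	0.00	0.00	0.00	0.00	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	frameshift allele; activity inferred null
3964delC	NA	NA	NA	NA	FALSE	TRUE	FALSE	0.00	0.00	0.00	0.00	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	deletion allele; activity inferred null
c.1064-1076del	NA	NA	NA	NA	FALSE	TRUE	FALSE	0.00	0.00	0.00	0.00	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	deletion allele; activity inferred null
1546dup10	NA	NA	NA	NA	FALSE	TRUE	FALSE	0.00	0.00	0.00	0.00	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	duplication frameshift allele; activity inferred null
8182delG	NA	NA	NA	NA	FALSE	TRUE	FALSE	0.00	0.00	0.00	0.00	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	deletion allele; activity inferred null
T325SfsX104	NA	NA	NA	NA	FALSE	TRUE	FALSE	0.00	0.00	0.00	0.00	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	frameshift allele; activity inferred null
R390H	390	R	H	NA	FALSE	FALSE	FALSE	NA	NA	NA	NA	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	missense partner allele; not assayed
P193L	193	P	L	NA	FALSE	FALSE	FALSE	NA	NA	NA	NA	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	missense partner allele; not assayed
P437L	437	P	L	NA	FALSE	FALSE	FALSE	NA	NA	NA	NA	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	missense partner allele; not assayed
G232R	232	G	R	NA	FALSE	FALSE	FALSE	NA	NA	NA	NA	NA	NONE	NA	NA	NA	NA	NA	NA	FALSE	missense partner allele; not assayed
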