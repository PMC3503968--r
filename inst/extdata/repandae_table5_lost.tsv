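# Parental SSAP bands lost in the allopolyploid taxa, as printed.
# in_all: parental bands missing from at least one polyploid taxon; its
# printed percentage and the per-taxon percentages are relative to the
# family's parental total.  Sharing-category printed percentages are relative
# to the family's in_all lost count.
te	in_all	in_NUD	in_REP	in_ISL	cat_NUD_REP_ISL	cat_NUD_REP	cat_NUD_ISL	cat_REP_ISL	cat_NUD	cat_REP	cat_ISL	pct_in_all	pct_in_NUD	pct_in_REP	pct_in_ISL	pct_cat_NUD_REP_ISL	pct_cat_NUD_REP	pct_cat_NUD_ISL	pct_cat_REP_ISL	pct_cat_NUD	pct_cat_REP	pct_cat_ISL
Au	71	49	57	55	35	3	8	9	3	10	3	81.6	56.3	65.5	63.2	49.3	4.2	11.3	12.7	4.2	14.1	4.2
TS	26	19	19	23	14	2	2	3	1	0	4	86.7	63.3	63.3	76.7	53.8	7.7	7.7	11.5	3.8	0	15.4
Ns1	58	36	43	42	24	1	9	5	2	13	4	87.9	54.5	65.2	63.6	41.4	1.7	15.5	8.6	3.4	22.4	6.9
Nt2	51	32	46	38	28	0	3	6	1	12	1	87.9	55.2	79.3	65.5	54.9	0	5.9	11.8	2	23.5	2
Tnt1	54	43	42	46	31	0	10	5	2	6	0	96.4	76.8	75	82.1	57.4	0	18.6	9.3	3.7	11.1	0
Tnt2	45	34	27	32	14	2	13	5	5	6	0	71.4	54	42.9	50.8	31.1	4.4	28.9	11.1	11.1	13.3	0
TRIM	46	39	32	33	24	2	7	1	6	5	1	69.7	59.1	48.5	50	52.2	4.3	15.2	2.2	13.0	10.9	2.2
All	351	252	266	269	170	10	52	34	20	52	13	82.4	59.2	62.4	63.1	48.4	2.8	14.8	9.7	5.7	14.8	3.4
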