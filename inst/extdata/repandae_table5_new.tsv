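# New (non-parental) SSAP bands in the allopolyploid taxa, as printed.
# in_all: bands new in at least one polyploid taxon; printed percentage is
# relative to the family's parental total.  Per-taxon (in_NUD/in_REP/in_ISL)
# and sharing-category counts; their printed percentages are relative to the
# family's in_all count.  Categories: subsets of {NUD, REP, ISL} in which the
# band is new.
te	in_all	in_NUD	in_REP	in_ISL	cat_NUD_REP_ISL	cat_NUD_REP	cat_NUD_ISL	cat_REP_ISL	cat_NUD	cat_REP	cat_ISL	pct_in_all	pct_in_NUD	pct_in_REP	pct_in_ISL	pct_cat_NUD_REP_ISL	pct_cat_NUD_REP	pct_cat_NUD_ISL	pct_cat_REP_ISL	pct_cat_NUD	pct_cat_REP	pct_cat_ISL
Au	21	17	11	12	3	6	7	0	1	2	2	24.1	81	52.4	57.1	14.3	28.6	33.3	0	4.8	9.5	9.5
TS	32	22	19	21	8	4	6	4	4	3	3	106	68.8	59.4	65.6	25	12.5	18.8	12.5	12.5	9.4	9.4
Ns1	23	17	9	14	3	0	10	1	4	5	0	34.8	73.9	39.1	60.9	13	0	43.5	4.3	17.4	21.7	0
Nt2	28	24	5	17	2	2	12	0	8	1	3	48.3	85.7	17.9	60.7	7.1	7.1	42.9	0	28.6	3.6	10.7
Tnt1	21	14	7	8	1	0	6	0	7	6	1	37.5	66.7	33.3	38.1	4.8	0	28.6	0	33.3	28.6	4.8
Tnt2	34	20	24	20	9	4	6	2	1	9	3	54.0	58.8	70.6	58.8	26.5	11.8	17.6	5.9	2.9	26.5	8.8
TRIM	11	8	9	7	4	2	2	1	0	2	0	16.7	72.7	81.8	63.6	36.4	18.2	18.2	9.1	0	18.2	0
All	170	122	82	99	30	18	49	8	25	28	12	39.9	71.8	48.2	58.2	17.6	10.6	28.8	4.7	14.7	16.5	7.1
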