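# Distribution of SSAP bands within and among the diploid progenitor taxa
# (TRI = N. obtusifolia, paternal; SYL = N. sylvestris, maternal), seven TE
# families.  Counts and the percentages exactly as printed in the source
# table; percentages of the totals row were not printed (NA).
te	total	shared	paternal_specific	maternal_specific	pct_shared	pct_paternal_specific	pct_maternal_specific
Au	87	15	37	35	17.2	42.5	40.2
TS	30	2	15	13	6.7	50.0	43.3
Ns1	66	10	18	38	15.1	27.3	57.6
Nt2	58	8	35	15	13.8	60.3	25.9
Tnt1	56	3	31	22	5.3	55.4	39.3
Tnt2	63	5	19	39	7.9	30.2	61.9
TRIM	66	11	30	25	16.6	45.5	37.9
All	426	54	185	187	NA	NA	NA
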