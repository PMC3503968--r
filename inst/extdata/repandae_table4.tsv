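# Proportions of SSAP bands deviating from expected diploid additivity in
# each allopolyploid taxon, with the printed 95% confidence bounds.  The
# denominator behind these printed proportions is not recoverable from the
# printed counts; the package therefore reports its own defined deviation
# proportion and never asserts equality with these cells (kept for reference).
te	taxon	proportion	ci_lower	ci_upper
Au	NUD	0.733	0.628	0.819
TS	NUD	0.953	0.830	0.992
Ns1	NUD	0.855	0.737	0.927
Nt2	NUD	0.767	0.651	0.855
Tnt1	NUD	0.851	0.738	0.922
Tnt2	NUD	0.900	0.788	0.959
TRIM	NUD	0.797	0.668	0.886
Au	REP	0.840	0.738	0.909
TS	REP	0.927	0.790	0.981
Ns1	REP	0.912	0.822	0.977
Nt2	REP	0.867	0.749	0.937
Tnt1	REP	0.875	0.753	0.944
Tnt2	REP	0.864	0.745	0.936
TRIM	REP	0.774	0.635	0.873
Au	ISL	0.817	0.713	0.891
TS	ISL	0.891	0.756	0.959
Ns1	ISL	0.903	0.795	0.960
Nt2	ISL	0.809	0.692	0.890
Tnt1	ISL	0.844	0.727	0.919
Tnt2	ISL	0.912	0.800	0.967
TRIM	ISL	0.769	0.628	0.870
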