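# One-way ANOVA on the distribution of new and lost SSAP bands among the
# seven sharing categories of polyploid taxa, as printed.
block	source	ss	df	ms	f	p
new	between	0.2855	6	0.0476	4.981	0.0006
new	within	0.4005	42	0.0096	NA	NA
lost	between	1.0436	6	0.1739	44.100	0.0001
lost	within	0.1656	42	0.0038	NA	NA
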