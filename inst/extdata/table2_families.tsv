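# Fertile/sterile counts per F2 family. n_total_printed is the published
# total column; family P20218 prints 97 although fertile + sterile = 87 --
# the inconsistency is preserved here and flagged, computations use the
# component sum.
season	family	n_total_printed	n_fertile	n_sterile	note
2020_autumn	P20210	66	53	13
2020_autumn	P20217	63	53	10
2020_autumn	P20218	97	65	22	printed_total_inconsistent
2021_spring	P211014	134	102	32
2021_spring	P211017	370	279	91
2021_spring	P211091	129	102	27
2021_spring	P211103	168	134	34
2021_spring	P211115	160	128	32
2021_spring	P211129	161	121	40
2021_spring	P211157	218	165	53
2021_spring	P211162	102	75	27
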