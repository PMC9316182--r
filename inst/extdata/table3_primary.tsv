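# Primary mapping: recombinant tallies among 45 sterile F2 plants.
# printed_cm is the published Kosambi distance for cross-checking.
marker	pos_bp	n_ho	n_he	n_total	printed_cm
P06g8405	203656182	3	0	45	6.71
P06g8077	212732221	2	1	45	5.58
P06g8089	204569609	2	0	45	4.46
P06g8229	208899271	0	2	45	2.22
P06g8264	209767667	0	0	45	0.00
P06g8490	214353887	0	0	45	0.00
P06g8494	214428701	0	0	45	0.00
P06g8497	214494826	0	0	45	0.00
P06g8536	215672797	0	0	45	0.00
P06g8527	215336423	0	0	45	0.00
P06g8560	215995316	0	1	45	1.11
P06g8618	216556879	2	0	45	4.46
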