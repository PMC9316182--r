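# Fine mapping: recombinant tallies among 336 sterile F2 plants. Only HE
# recombinants were printed for this stage; HO defaults to 0.
marker	pos_bp	n_ho	n_he	n_total	printed_cm
P06g8229	208899271	0	43	336	6.43
P06g8335	210959629	0	35	336	5.23
P06g8405	212732234	0	24	336	3.58
P06g8434	213257869	0	23	336	3.43
P06g8219	208736376	0	22	336	3.28
P06gInDel-15	213906630	0	20	336	2.98
P06g8528	215338579	0	6	336	0.89
P06gInDel-38	214431109	0	4	336	0.60
P06g8490	214353887	0	4	336	0.60
P06g8499	214498896	0	4	336	0.60
P06g8508	214872305	0	3	336	0.45
P06gInDel-46	214885975	0	2	336	0.30
P06gInDel-48	214903798	0	2	336	0.30
P06gInDel-56	214950959	0	2	336	0.30
P06gInDel-66	215097259	0	1	336	0.15
P06g8527	215336423	0	0	336	0.00
P06gInDel-79	215419831	0	0	336	0.00
P06gInDel-81	215498386	0	0	336	0.00
P06gInDel-89	215631069	0	1	336	0.15
P06gInDel-90	215633948	0	1	336	0.15
P06gInDel-91	215636889	0	2	336	0.30
P06gInDel-92	215669032	0	2	336	0.30
P06gInDel-94	215669384	0	2	336	0.30
P06gInDel-95	215674072	0	2	336	0.30
P06g8543	215710422	0	3	336	0.45
P06gInDel-99	215741617	0	3	336	0.45
P06g8549	215773438	0	3	336	0.45
P06g8560	215995331	0	6	336	0.89
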