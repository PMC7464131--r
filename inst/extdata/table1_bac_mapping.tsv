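bac_id	bac_size	bionano_scaffold	ncbi_scaffold	scaffold_size	cpi_chromosome
424K2	163122	203	ML621420.1	15883268	1p
318H23	145864	217	ML621429.1	8721052	1p
537D7	154142	60	ML621305.1	21088589	1q
168O10	162311	153	ML621386.1	8440838	1q
470O22	158668	331	ML621495.1	5731011	1q
225M17	149235	179	ML621405.1	57448544	2p
106D24	132359	23	ML621269.1	31217720	2p
470J13	136853	304	ML621480.1	3056537	2p
380G19	160060	141	ML621375.1	5625148	4q
318A2	138653	60	ML621305.1	21088589	4q
500C11	176356	29527	ML621534.1	1293745	5p
105C15	151304	87	ML621330.1	5648650	5q
318A22	134050	163	ML621393.1	21409697	5q
225A1	149859	178	ML621404.1	40323178	6
424G4	146986	75	ML621319.1	13166690	7
423F21	152254	75	ML621319.1	13166690	7
125H10	146876	18	ML621264.1	1390666	8p
318N9	153773	76	ML621320.1	21927555	8p
431J7	125453	309	ML621483.1	5421227	8q
443C11	136412	194	ML621413.1	18639614	9p
318D7	137214	14	ML621260.1	13251999	9q
457H22	146712	126	ML621362.1	19176785	13
380O21	149406	120	ML621356.1	1852121	15
428I15	135794	145	ML621378.1	23325489	17
421D7	172285	56	ML621301.1	6383505	18
146H23	170310	177	ML621403.1	1209793	19
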