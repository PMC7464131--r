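bionano_scaffold	ncbi_scaffold	scaffold_size	bac_id	chromosome	evidence_source
60	ML621305.1	21088589	537D7	1q	de_novo
60	ML621305.1	21088589	106H12	4	previous
153	ML621386.1	8440838	168O10	1q	de_novo
153	ML621386.1	8440838	116H12	22	previous
163	ML621393.1	21409697	318A22	5q	de_novo
163	ML621393.1	21409697	38H12	8	previous
178	ML621404.1	40323178	225A1	6	de_novo
178	ML621404.1	40323178	63H12	4	previous
15	ML621261.1	59628869	15H12	5	previous
15	ML621261.1	59628869	72H12	6	previous
15	ML621261.1	59628869	35H18	6	previous
70	ML621314.1	11495585	147L13	1	previous
70	ML621314.1	11495585	27H12	11	previous
207	ML621424.1	27887944	45H12	1	previous
207	ML621424.1	27887944	55A6	1	previous
207	ML621424.1	27887944	26H12	13	previous
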