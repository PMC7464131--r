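bionano_scaffold	ncbi_scaffold	gene	cpi_chromosome	gga_chromosome	newly_identified
289	ML621472.1	Fhl2	1	1	no
70	ML621314.1	Dax1	1	1	no
207	ML621424.1	Fgf9	1	1	no
339	ML621502.1	Ctnnb1	2	2	yes
65	ML621310.1	Sox9	3	18	no
65	ML621310.1	Esr1	3	3	yes
135	ML621369.1	Gata4	3	3	no
330	ML621494.1	Wt1	4	5	no
59	ML621304.1	Gata2	5	12	yes
15	ML621261.1	Emx2	5	6	yes
75	ML621319.1	Aco1	7	Z	yes
128	ML621363.1	Dmrt1	7	Z	no
128	ML621363.1	Dmrt2	7	Z	yes
128	ML621363.1	Rps6	7	Z	yes
163	ML621393.1	Lhx9	8	8	yes
309	ML621483.1	Dmrtb1	8	8	yes
4	ML621250.1	Foxl2	9	9	no
145	ML621378.1	Gpn3	17	15	yes
198	ML621416.1	Rspo1	18	23	no
83	ML621327.1	Sf1	20	17	no
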