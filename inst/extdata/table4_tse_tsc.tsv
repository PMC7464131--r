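bac_id	tse_scaffold	tse_chromosome	tsc_chromosome
68H12	CM023056.1	1	1
7H12	CM023056.1	1	1
67H12	CM023058.1	3	1
O34H12	CM023056.1	1	1
61H12	CM023056.1	1	1
45H12	CM023056.1	1	1
113H12	CM023056.1	1	1
14H12	CM023057.1	2	2
99H12	CM023057.1	2	2
5H12	CM023057.1	2	2
25H12	CM023057.1	2	2
96H12	CM023057.1	2	2
4H12	CM023057.1	2	2
125H12	CM023058.1	3	3
53H12	CM023058.1	3	3
82H12	CM023058.1	3	3
104H12	CM023058.1	3	3
31H12	CM023058.1	3	3
94H12	CM023059.1	4	4
85H12	CM023059.1	4	4
88H12	CM023059.1	4	4
6H12	CM023059.1	4	4
63H12	CM023059.1	4	4
106H12	CM023059.1	4	4
120H12	CM023060.1	5	5
33H12	CM023060.1	5	5
72H12	CM023060.1	5	5
9H12	CM023058.1	3	6
122H12	CM023061.1	6	6
114H12	CM023062.1	7	7
60H12	CM023062.1	7	7
15H12	CM023062.1	7	7
3H12	CM023063.1	8	8
54H12	CM023063.1	8	8
40H12	CM023063.1	8	8
38H12	CM023063.1	8	8
105H12	CM023063.1	8	8
123H12	CM023063.1	8	8
78H12	CM023064.1	9	9
89H12	CM023064.1	9	9
29H12	CM023065.1	10	10
27H12	CM023066.1	11	11
100H12	CM023069.1	14	13
26H12	CM023069.1	14	13
118H12	CM023068.1	13	15
121H12	CM023075.1	20	18
12H12	CM023058.1	3	19
28H12	CM023074.1	19	24
52H12	CM023071.1	16	21
116H12	CM023077.1	22	22
16H12	CM023071.1	16	25
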