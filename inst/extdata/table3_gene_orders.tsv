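species	chromosome	rank	gene
CPI	1	1	Fhl2
CPI	1	2	Dax1
CPI	1	3	Fgf9
GGA	1	1	Dax1
GGA	1	2	Fhl2
GGA	1	3	Fgf9
CPI	3	1	Sox9
CPI	3	2	Esr1
CPI	3	3	Gata4
GGA	3	1	Esr1
GGA	3	2	Gata4
GGA	18	1	Sox9
CPI	5	1	Gata2
CPI	5	2	Emx2
GGA	12	1	Gata2
GGA	6	1	Emx2
CPI	7	1	Aco1
CPI	7	2	Dmrt1
CPI	7	3	Dmrt2
CPI	7	4	Rps6
GGA	Z	1	Dmrt1
GGA	Z	2	Dmrt2
GGA	Z	3	Rps6
GGA	Z	4	Aco1
CPI	8	1	Lhx9
CPI	8	2	Dmrtb1
GGA	8	1	Lhx9
GGA	8	2	Dmrtb1
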