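chrom	pos	ref	alt	g_ref	g_alt	y_ref	y_alt
D10	2e+05	A	T	17	13	1	34
D10	4e+05	A	G	22	17	0	39
D10	6e+05	T	C	18	12	0	32
D10	8e+05	C	A	24	10	1	34
D10	1e+06	G	T	20	17	0	36
D10	1200000	A	G	21	14	0	38
D10	1400000	G	C	21	11	0	35
D10	1600000	G	C	20	14	0	33
D10	1800000	T	G	22	9	0	34
D10	2e+06	A	G	23	10	0	40
D10	2200000	T	A	21	13	1	36
D10	2400000	C	A	17	16	0	22
D10	2600000	G	C	17	15	0	43
D10	2800000	G	T	26	14	0	36
D10	3e+06	A	C	19	12	2	24
D10	3200000	G	C	25	12	0	38
D10	3400000	T	C	17	18	0	29
D10	3600000	G	T	22	5	0	28
D10	3800000	G	C	27	17	3	32
D10	4e+06	T	A	18	13	2	32
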