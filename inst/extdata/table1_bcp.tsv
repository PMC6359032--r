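#! table: bcp
#! unit: a.u.
# rho_printed / g_printed keep the verbatim printed strings; rho and g hold
# the values used for computation. The two acetic-acid cells flagged
# decimal_typo print 0.2266 / 0.2262 but the local virial relation fixes
# them to 0.02266 / 0.02262 (shifted decimal point).
molecule	medium	bond	rho_printed	lap	v	g_printed	rho	g	h_bcp	e_hb_kj	length	angle	flag
Neu5Gc	Gas	O2-H31...O9	0.02953	0.1126	-0.02557	0.02687	0.02953	0.02687	0.001301	-33.56	2.794	4.804	
Neu5Gc	Gas	O3-H34...O1	0.02885	0.1327	-0.02784	0.03050	0.02885	0.03050	0.002673	-36.55	2.524	6.080	
Neu5Gc	Gas	O10-H41...O9	0.02385	0.1051	-0.02086	0.02357	0.02385	0.02357	0.002710	-27.39	2.646	13.65	
Neu5Gc	Gas	N11-H30...O5	0.02255	0.09263	-0.01774	0.02045	0.02255	0.02045	0.002705	-23.29	2.921	2.811	
Neu5Gc	Acetic acid	O10-H41...O9	0.2266	0.1019	-0.01975	0.2262	0.02266	0.02262	0.002869	-25.94	2.653	4.951	decimal_typo
Neu5Gc	Benzene	O10-H41...O9	0.02319	0.1038	-0.02031	0.02313	0.02319	0.02313	0.002817	-26.67	2.652	5.516	
Neu5Ac	Gas	O3-H33...O1	0.02262	0.1058	-0.02053	0.02349	0.02262	0.02349	0.002964	-26.95	2.586	8.897	
Neu5Ac	Gas	O2-H30...O9	0.02907	0.1101	-0.02485	0.02619	0.02907	0.02619	0.001343	-32.62	2.800	4.906	
Neu5Ac	Acetic acid	O2-H30...O9	0.02361	0.08990	-0.01891	0.02069	0.02361	0.02069	0.001782	-24.82	2.850	5.233	
Neu5Ac	Benzene	O3-H33...O1	0.02027	0.09740	-0.01829	0.02132	0.02027	0.02132	0.003026	-24.02	2.625	11.40	
Neu5Ac	Benzene	O2-H30...O9	0.02818	0.1064	-0.02373	0.02518	0.02818	0.02518	0.001443	-31.16	2.816	4.511	
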