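index	protein	uniprot	site	sequence
1	ATRIP	Q8WXE1	S224	VSHVSPRKNPSV
2	BRCA1	P38398	S1497	VERSSPSKCPSL
3	CDKN2D	P55273	S76	SGTSPVHDAAR
4	CROCC iso2	Q5TZA2-2	S763	PVPGSPARDAPA
5	Ctip	Q99708	T847	IPPNTPENFWEV
6	DLG1	Q12959	S158	HSHISPIKPTEA
7	DLG1	Q12959	S443	QTPASPARYSPV
8	EZH2	Q15910	T345	ERIKTPPKRPGG
9	FOXM1 iso2	Q08050-2	T596	PISSTPSKSVLP
10	FOXO1A	Q12778	S249	KSGKSPRRRAAS
11	HIRA	P54198	T555	SVLTTPSKIEPM
12	HR6A	P49459	S120	PNPNSPANSQAA
13	ID3	Q02535	S5	MKALSPVRGCYE
14	ING5	Q8WYH8	T152	EEEDTPKKKKHK
15	LIG3	P49916	S210	GQVTSPVKGASF
16	ORC2	Q13416	T116	ELAKTPQKSVSF
17	ORC2	Q13416	T226	VGKETPSKRMKR
18	p27	P46527	T187	SVEQTPKKPGLR
19	p63	Q9H3D4	T491	RNALTPTTIPDG
20	p73	O15350	T86	ASPYTPEHAASV
21	PELP1	Q8IZL8	S991	PPPESPPKVQPE
22	PLZF	Q05516	S197	LSAMSPTKAAVD
23	PLZF	Q05516	T282	EGPGTPTRSSVI
24	PTPN2 iso2	P17706-2	S304	AFDHSPNKIMTE
25	RbBP1	P29374	S864	LGQSSPEKKIRI
26	RbBP1	P29374	S1007	FSVASPLTLSQD
27	RPL12	P30050	S38	PLGLSPKKVGDD
28	SIRT2	Q8IXJ6	S368	STSASPKKSPPP
29	Smad3	P84022	T8	ILPFTPPIVKRL
30	Smad3	P84022	T179	NIPETPPPGYLS
31	Smad3	P84022	S213	PNPMSPAHNNLD
32	SMRT	Q9T618	S1259	IGEDSPSRLDRG
33	SMRT	Q9T618	T1463	ITQGTPLKYDTG
34	SMRT	Q9T618	S1487	SLIGSPGRTFPP
35	NBS1	Q9NX02	S432	NYQLSPTKLPSI
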