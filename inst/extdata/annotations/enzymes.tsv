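accession	gene	enzyme_class	residue	position	site_effect
P07948	LYN	kinase	.	.	.
P07948	LYN	kinase	Y	397	induces
P06239	LCK	kinase	.	.	.
P06239	LCK	kinase	Y	394	induces
P15056	BRAF	kinase	.	.	.
P15056	BRAF	kinase	S	729	induces
P27361	MAPK3	kinase	.	.	.
P27361	MAPK3	kinase	T	207	inhibits
Q13131	PRKAA1	kinase	.	.	.
Q13131	PRKAA1	kinase	S	496	inhibits
P35269	GTF2F1	kinase	.	.	.
P35269	GTF2F1	kinase	S	385	inhibits
Q05655	PRKCD	kinase	.	.	.
Q13177	PAK2	kinase	.	.	.
P10398	ARAF	kinase	.	.	.
Q13233	MAP3K1	kinase	.	.	.
Q9H792	PEAK1	kinase	.	.	.
Q96GX5	MASTL	kinase	.	.	.
O00750	PIK3C2B	kinase	.	.	.
P04626	ERBB2	kinase	.	.	.
P18669	PGAM1	phosphatase	.	.	.
Q9C0I1	MTMR12	phosphatase	.	.	.
O15355	PPM1G	phosphatase	.	.	.
Q05209	PTPN12	phosphatase	.	.	.
Q96T60	PNKP	phosphatase	.	.	.
Q96T60	PNKP	phosphatase	S	114	both
Q92539	LPIN2	phosphatase	.	.	.
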