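anchor_accession	partner_accession	partner_gene	source	evidence
P07947	P07948	LYN	synthetic-curated	binary
P07947	P06239	LCK	synthetic-curated	binary
P07947	P04626	ERBB2	synthetic-curated	binary
P07947	P22681	CBL	synthetic-curated	binary
P07947	Q13263	TRIM28	synthetic-curated	binary
P07947	Q13435	SF3B2	synthetic-curated	binary
P07947	P15311	EZR	synthetic-curated	binary
P07947	P04792	HSPB1	synthetic-curated	binary
P07947	Q9UHB6	LIMA1	synthetic-curated	binary
P07947	P17987	TCP1	synthetic-curated	binary
P07947	P55196	AFDN	synthetic-curated	binary
P07947	O15042	U2SURP	synthetic-curated	binary
P07947	Q4G0J3	LARP7	synthetic-curated	binary
P07947	P40227	CCT6A	synthetic-curated	binary
P07947	Q96I25	RBM17	synthetic-curated	binary
P07947	P02794	FTH1	synthetic-curated	binary
P07947	P17302	GJA1	synthetic-curated	binary
P07947	Q13480	GAB1	synthetic-curated	binary
P07947	Q13177	PAK2	synthetic-curated	binary
P07947	Q9UPQ0	LIMCH1	synthetic-curated	binary
P07947	P46937	YAP1	synthetic-curated	binary
P07947	P35222	CTNNB1	synthetic-curated	binary
P07947	P00533	EGFR	synthetic-curated	binary
P07947	P12931	SRC	synthetic-curated	binary
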