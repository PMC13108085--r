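kinase_accession	kinase_gene	substrate_accession	substrate_gene	substrate_residue	substrate_position	evidence_class	source
P06239	LCK	P07947	YES1	Y	426	screen	synthetic-htp-screen
P06239	LCK	P07947	YES1	Y	426	predicted	synthetic-motif-pred
P07948	LYN	P07947	YES1	Y	426	predicted	synthetic-motif-pred
P04626	ERBB2	P07947	YES1	Y	426	predicted	synthetic-motif-pred
P12931	SRC	P07947	YES1	Y	32	experimental	synthetic-curated
P07947	YES1	P06239	LCK	Y	394	predicted	synthetic-motif-pred
P07947	YES1	P07948	LYN	Y	397	experimental	synthetic-curated
P07947	YES1	Q13443	ADAM9	Y	769	predicted	synthetic-motif-pred
P07947	YES1	Q9NWQ8	PAG1	Y	227	predicted	synthetic-motif-pred
P07947	YES1	P68104	EEF1A1	Y	141	screen	synthetic-htp-screen
P07947	YES1	P10398	ARAF	Y	155	predicted	synthetic-motif-pred
P07947	YES1	P52799	EFNB2	Y	304	predicted	synthetic-motif-pred
P07947	YES1	Q6NZI2	CAVIN1	Y	308	screen	synthetic-htp-screen
P07947	YES1	P07948	LYN	Y	306	predicted	synthetic-motif-pred
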