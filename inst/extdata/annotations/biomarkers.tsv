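disease	gene	source
breast cancer	YBX1	synthetic-curated
breast cancer	CRK	synthetic-curated
breast cancer	ERBB2	synthetic-curated
leukemia	LYN	synthetic-curated
leukemia	PRKCD	synthetic-curated
leukemia	ZFP36	synthetic-curated
colorectal cancer	BRAF	synthetic-curated
colorectal cancer	EXO1	synthetic-curated
lung adenocarcinoma	VDAC1	synthetic-curated
lung adenocarcinoma	MAPK3	synthetic-curated
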