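mirna_id	gene	source_db
hsa-miR-34a-5p	EGFR	mirnet
hsa-miR-34a-5p	ERBB2	mirnet
hsa-miR-34a-5p	JUN	mirnet
hsa-miR-34a-5p	ETS1	mirnet
hsa-miR-34a-5p	MYC	mirnet
hsa-miR-34a-5p	MKI67	mirnet
hsa-miR-34a-5p	TP53	mirnet
hsa-miR-34a-5p	CDKN2A	mirnet
hsa-miR-34a-5p	FGFR2	mirnet
hsa-miR-34a-5p	FGFR3	mirnet
hsa-miR-34a-5p	BCL2	mirnet
hsa-miR-124-3p	EGFR	mirnet
hsa-miR-124-3p	ERBB2	mirnet
hsa-miR-124-3p	JUN	mirnet
hsa-miR-124-3p	ETS1	mirnet
hsa-miR-124-3p	MYC	mirnet
hsa-miR-124-3p	MKI67	mirnet
hsa-miR-124-3p	CDKN2A	mirnet
hsa-miR-124-3p	FGFR3	mirnet
hsa-miR-125b-5p	EGFR	mirnet
hsa-miR-125b-5p	ERBB2	mirnet
hsa-miR-125b-5p	JUN	mirnet
hsa-miR-125b-5p	ETS1	mirnet
hsa-miR-125b-5p	MKI67	mirnet
hsa-miR-125b-5p	TP53	mirnet
hsa-miR-125b-5p	CDKN2A	mirnet
hsa-miR-125b-5p	FGFR2	mirnet
hsa-miR-1-3p	EGFR	mirnet
hsa-miR-1-3p	FGFR2	mirnet
hsa-miR-1-3p	ETS1	mirnet
hsa-miR-1-3p	MYC	mirnet
hsa-miR-1-3p	JUN	mirnet
hsa-miR-1-3p	TP53	mirnet
hsa-miR-1-3p	MKI67	mirnet
hsa-miR-147a	EGFR	mirnet
hsa-miR-147a	FGFR2	mirnet
hsa-miR-147a	ETS1	mirnet
hsa-miR-147a	JUN	mirnet
hsa-miR-155-5p	CDKN2A	mirnet
hsa-miR-155-5p	BCL2	mirnet
hsa-miR-423-3p	CDKN2A	mirnet
hsa-miR-423-3p	BCL2	mirnet
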