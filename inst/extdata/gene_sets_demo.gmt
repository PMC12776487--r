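DEMO_LIMB_MORPHOGENESIS	synthetic demo set: limb morphogenesis	TP63	FGFR2	DLG1	MYH3	NIPBL	GLI3	HOXD13	TWIST1	SHH	GREM1	FGF8	WNT7A	SALL4	TBX5	HAND2
DEMO_CRANIOFACIAL_DEVELOPMENT	synthetic demo set: craniofacial development	TP63	FGFR2	NIPBL	DLG1	IRF6	MSX1	PAX9	SATB2	SOX9	FOXE1	TFAP2A	BMP4	SPRY2	ARHGAP29	CTNNA2
DEMO_CHROMATIN_REGULATION	synthetic demo set: chromatin and recombination	PRDM9	NIPBL	SMC1A	SMC3	HDAC8	RAD21	CTCF	SETD2	KMT2D	KDM6A	EP300	CREBBP
DEMO_UBIQUITIN_PATHWAY	synthetic demo set: ubiquitin ligase activity	TRIM73	TRIM74	TRIM50	UBE2A	UBE3A	CUL3	RNF213	MARCH7	HERC2	UBR1
DEMO_CARDIAC_MUSCLE	synthetic demo set: cardiac and skeletal muscle	ANKRD1	MYH3	MYH7	TTN	TNNT2	ACTC1	MYBPC3	DES	LMNA	TPM1
DEMO_HOUSEKEEPING	synthetic demo set: unrelated background	GAPDH	ACTB	TUBB	RPL13A	RPS18	B2M	HPRT1	TBP	UBC	PGK1	PPIA	YWHAZ	SDHA	GUSB	HMBS	EEF1A1	RPLP0	TFRC	POLR2A	CYC1
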