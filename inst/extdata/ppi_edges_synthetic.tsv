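protein1	protein2	combined_score
TP63	DLG1	310
TP63	FGFR2	460
DLG1	MYH3	220
MYH3	ANKRD1	190
RGPD5	NIPBL	160
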