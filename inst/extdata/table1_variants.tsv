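family_id	proband_sex	gene	reported_inheritance	chrom	pos	dbsnp_id	ref	alt	hgvs_c	hgvs_p	consequence	zygosity	n_tools_pathogenic	cadd_phred	maf_kg1000	maf_esp	maf_gnomad	mother_affected	father_present	gt_mother	gt_father
F1	XY	RGPD5	de_novo	chr2	109837829	rs1553471918	G	A	c.4708G>A	p.Gly1570Arg	missense	het	7	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F1	XY	FAM90A26	de_novo	chr4	9173181	rs1450748908	AC	A	c.10del	p.Cys4ValfsTer12	frameshift	hom_alt	NA	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F2	XY	FOXD4L1	de_novo	chr2	113499585	rs201655302	A	C	c.329A>C	p.Tyr110Ser	missense	het	9	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F2	XY	FAM170A	de_novo	chr5	119634539	rs754719389	T	C	c.791T>C	p.Met264Thr	missense	het	7	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F2	XY	DLG1	de_novo	chr3	197090942	rs769502806	G	A	c.1730G>A	p.Arg577Gln	missense	het	6	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F2	XY	ANKRD1	de_novo	chr10	90917812	rs773773073	C	T	c.472C>T	p.His158Tyr	missense	het	11	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F3	XX	TP63	de_novo	chr3	189868614	rs886041251	C	T	c.1027C>T	p.Arg343Trp	missense	het	11	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F4	XX	NIPBL	unknown	chr5	37059093	NOVEL	GCT	G	c.7617_7618del	p.Ser2540ProfsTer21	frameshift	het	NA	NA	NA	NA	NA	FALSE	FALSE	hom_ref	missing
F5	XX	MYH3	de_novo	chr17	10641317	rs121913617	G	A	c.2015G>A	p.Arg672His	missense	het	9	NA	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F6	XX	FGFR2	unknown	chr10	121520163	rs79184941	C	G	c.755C>G	p.Ser252Trp	missense	het	10	NA	NA	NA	0.00001	FALSE	FALSE	hom_ref	missing
F7	XY	TRIM74	de_novo	chr7	72961358	rs199887265	C	T	c.487C>T	p.Arg163Ter	stop_gained	het	NA	35	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F7	XY	TRIM73	de_novo	chr7	75403732	rs199982097	C	T	c.487C>T	p.Arg163Ter	stop_gained	het	NA	35	NA	NA	0.00001	FALSE	TRUE	hom_ref	hom_ref
F8	XY	PRDM9	de_novo	chr5	23527360	NOVEL	A	ATG	c.2272_2273insTG	p.Arg758LeufsTer182	frameshift	hom_alt	NA	NA	NA	NA	NA	FALSE	TRUE	hom_ref	hom_ref
F9	XX	TP63	maternal	chr3	189867902	rs1205536026	C	T	c.952C>T	p.Arg318Cys	missense	het	11	NA	NA	NA	0.00001	TRUE	TRUE	het	hom_ref
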