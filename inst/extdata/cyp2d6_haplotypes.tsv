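# Built-in CYP2D6 haplotype definition table.
# One row per star allele (or sub-allele); site columns hold ref/var/na
# state codes (na = state undefined for this haplotype, e.g. sequence
# on the CYP2D7-derived side of a hybrid switch region).
star_name	gene	structural_kind	switch_interval	tandem_partners	activity	rs1080985	rs769258	rs1065852	rs5030862	137_138insT	883G>C	rs28371706	rs61736512	rs5030655	1758G>T	1758G>A	rs3892097	1863_1864ins(TTTCGCCCC)1	rs72549356	1973_1974insG	2539_2542delAACT	rs35742686	rs5030656	rs16947	rs5030867	rs28371725	3184G>A	3199C>G	3277T>C	4043G>A	rs1135840
*1	CYP2D6	full_gene			1	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*2	CYP2D6	full_gene			1	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*2.001	CYP2D6	full_gene			1	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*3	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref
*4	CYP2D6	full_gene			0	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var
*4.013	CYP2D6	hybrid_2D6_2D7	intron6:exon9	*4	0	ref	ref	var	ref	var	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	na
*5	CYP2D6	deletion			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*6	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*7	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref
*8	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*9	CYP2D6	full_gene			0.5	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref
*10	CYP2D6	full_gene			0.25	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var
*11	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*12	CYP2D6	full_gene			0	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*13	CYP2D6	hybrid_2D7_2D6	intron2:intron6		0	ref	var	ref	ref	var	ref	ref	na	na	na	na	na	na	na	na	na	na	na	na	na	na	na	na	na	na	na
*13[EU093102]	CYP2D6	hybrid_2D7_2D6	intron2:intron6		0	ref	var	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	na	ref	ref	ref	ref	var
*13[GQ162807]	CYP2D6	hybrid_2D7_2D6	intron2:intron6	*2	0	ref	var	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*14	CYP2D6	full_gene			0.5	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*15	CYP2D6	full_gene			0	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*17	CYP2D6	full_gene			0.5	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*19	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*20	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*25	CYP2D6	full_gene			uncertain	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref
*26	CYP2D6	full_gene			uncertain	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref
*29	CYP2D6	full_gene			0.5	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	var	ref	ref	ref	var
*30	CYP2D6	full_gene			uncertain	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*31	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	var	var
*35	CYP2D6	full_gene			1	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*36	CYP2D6	hybrid_2D6_2D7	intron6:exon9	*10	0	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	na
*39.001	CYP2D6	full_gene			1	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var
*40	CYP2D6	full_gene			0	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
*41	CYP2D6	full_gene			0.25	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	var	ref	ref	ref	ref	var
*57	CYP2D6	hybrid_2D6_2D7	intron6:exon9		0	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	na
*61	CYP2D6	hybrid_2D6_2D7	intron6:exon9		0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*63	CYP2D6	hybrid_2D6_2D7	intron6:exon9		0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*68	CYP2D6	hybrid_2D6_2D7	five_prime_flank:intron2	*4	0	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*69	CYP2D6	full_gene			0	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	var	ref	ref	ref	ref	var
*83	CYP2D6	hybrid_2D6_2D7	intron2:intron6		0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*114	CYP2D6	full_gene			0	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	var
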