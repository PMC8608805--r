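# Built-in variant site registry: canonical id (rsID where available),
# legacy-label aliases (both M33388 numbering dialects), gene position for
# 5'->3' ordering, and location relative to the CNV probe regions.
canonical_id	gene	position	region	aliases	ref_state	var_state
rs1080985	CYP2D6	-1584	five_prime_flank	-1584C>G	C	G
rs769258	CYP2D6	31	exon1_intron2	31G>A	G	A
rs1065852	CYP2D6	100	exon1_intron2	100C>T	C	T
rs5030862	CYP2D6	124	exon1_intron2	124G>A	G	A
137_138insT	CYP2D6	137	exon1_intron2	138insT	-	insT
883G>C	CYP2D6	883	exon1_intron2	882G>C	G	C
rs28371706	CYP2D6	1023	exon1_intron2	1023C>T	C	T
rs61736512	CYP2D6	1660	intron2_intron6	1660G>A,1659G>A	G	A
rs5030655	CYP2D6	1708	intron2_intron6	1708delT,1707delT	T	del
1758G>T	CYP2D6	1758	intron2_intron6	1759G>T	G	T
1758G>A	CYP2D6	1758	intron2_intron6	1759G>A	G	A
rs3892097	CYP2D6	1847	intron2_intron6	1847G>A,1846G>A	G	A
1863_1864ins(TTTCGCCCC)1	CYP2D6	1863	intron2_intron6		-	ins9
rs72549356	CYP2D6	1863	intron2_intron6	1863_1864ins(TTTCGCCCC)2	-	ins18
1973_1974insG	CYP2D6	1973	intron2_intron6	1973insG	-	insG
2539_2542delAACT	CYP2D6	2539	intron2_intron6		AACT	del
rs35742686	CYP2D6	2550	intron2_intron6	2550delA,2549delA	A	del
rs5030656	CYP2D6	2616	intron2_intron6	2616delAAG,2615delAAG	AAG	del
rs16947	CYP2D6	2851	intron2_intron6	2851C>T,2850C>T	C	T
rs5030867	CYP2D6	2936	intron2_intron6	2936A>C,2935A>C	A	C
rs28371725	CYP2D6	2989	intron2_intron6	2989G>A,2988G>A	G	A
3184G>A	CYP2D6	3184	intron6_exon9	3183G>A	G	A
3199C>G	CYP2D6	3199	intron6_exon9	3198C>G	C	G
3277T>C	CYP2D6	3277	intron6_exon9	3276T>C	T	C
4043G>A	CYP2D6	4043	intron6_exon9	4042G>A	G	A
rs1135840	CYP2D6	4181	intron6_exon9	4181G>C,4180G>C	G	C
rs12248560	CYP2C19	-806	five_prime_flank	-806C>T	C	T
rs28399504	CYP2C19	1		1A>G	A	G
rs41291556	CYP2C19	358		358T>C	T	C
rs72552267	CYP2C19	395		395G>A	G	A
rs17884712	CYP2C19	431		431G>A	G	A
rs374036992	CYP2C19	463		463G>T	G	T
rs4986893	CYP2C19	636		636G>A	G	A
rs6413438	CYP2C19	680		680C>T	C	T
rs4244285	CYP2C19	681		681G>A,19154G>A	G	A
rs56337013	CYP2C19	1297		1297C>T	C	T
rs72558186	CYP2C19	19294		19294T>A	T	A
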