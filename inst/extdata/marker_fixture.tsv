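# Curated TATA-box SNP marker table (32 variant rows).
# The published tables typeset the wt/mut KD column merged (e.g. "52" = wt 5,
# mut 2 nM); the un-merging here was done once, by hand, pinned by the prose
# anchors (IL1B 5->2, CETP deletion 4->7, DHFR 15->9, HBB 5->21 / 5->29) and
# the rule that direction 'up' means KD decreases. alpha is the printed
# ladder bound. Unregistered variants carry stable synthetic ids.
table_id	gene	omim_id	rs_id	flank5	ref	alts	flank3	kd_wt_nM	kd_mut_nM	direction	z_printed	alpha_printed	note	annotation
T1	IL1B	147720	rs1143627	ttttgaaagc	c	t	ataaaaacag	5	2	up	15	1e-06	worked example: -31C>T converts CATAAAA to the canonical TATAAAA	Graves disease; gastric/liver/lung cancers; recurrent depression; cachexia in rheumatoid arthritis (hypothetical)
T1	IL1B	147720	rs549858786	tgaaagccat	a	t	aaaacagcga	5	7	down	8	1e-06		rheumatoid arthritis (hypothetical)
T1	INS	176730	rs5505	agatcactgt	c	t	cttctgccat	53	44	up	4	0.001		type 1 diabetes after neonatal diabetes mellitus
T1	INS	176730	rs563207167	tcagccctgc	c	t	tgtctcccag	53	44	up	4	0.001		type 1 diabetes after neonatal diabetes mellitus (hypothetical)
T1	INS	176730	rs11557611	gatcactgtc	c	t	ttctgccatg	53	60	down	2	0.05		demyelinating diseases (hypothetical)
T1	CETP	118470	CETP:del18@-72	cgtgggggct	gggcggacatacatatac	-	gggctccagg	4	7	down	7	1e-06	wt allele printed as '18 bp-'; deleted segment transcribed verbatim from the G-72..C-54 prose (18 bp as labelled, though the printed -72..-54 span would cover 19 positions)	hyperalphalipoproteinemia reducing atherosclerosis risk
T1	CETP	118470	rs17231520	ggggctgggc	g	a	gacatacata	4	2	up	10	1e-06		hypoalphalipoproteinemia; atherosclerosis-related autoimmune and coronary diseases (hypothetical)
T1	CETP	118470	rs569033466	atacatatac	g	a	ggctccaggc	4	3	up	4	0.001		hypoalphalipoproteinemia; atherosclerosis-related autoimmune and coronary diseases (hypothetical)
T1	MMP12	601046	rs2276109	gatatcaact	a	g	tgagtcactc	11	14	down	3	0.01		low risk of asthma and systemic sclerosis; psoriasis (hypothetical)
T1	MMP12	601046	rs572527200	gatgatatca	a	g	ctatgagtca	11	14	down	3	0.01		low risk of systemic sclerosis, psoriasis, asthma (hypothetical)
T2	HBD	142000	rs35518301	caggaccagc	a	g	taaaaggcag	4	8	down	11	1e-06		malaria resistance; delta-thalassemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBD	142000	rs34166473	aggaccagca	t	c	aaaaggcagg	4	8	down	18	1e-06		Cooley's anemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs34500389	cagggctggg	c	a,t,g	ataaaagtca	5	6	down	3	0.01		malaria resistance; beta-thalassemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs33981098	agggctgggc	a	g,c	taaaagtcag	5	9	down	10	1e-06		malaria resistance; beta-thalassemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs33980857	gggctgggca	t	a,g,c	atacaacagt	5	21	down	27	1e-06		malaria resistance; beta-thalassemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs397509430	gggctgggca	t	-	atacaacagt	5	29	down	34	1e-06		malaria resistance; beta-thalassemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs34598529	ggctgggcat	a	g	aaagtcaggg	5	18	down	24	1e-06		malaria resistance; beta-thalassemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs33931746	gctgggcata	a	g,c	aagtcagggc	5	11	down	14	1e-06		malaria resistance; beta-thalassemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs281864525	tgggcataaa	a	c	gtcagggcag	5	7	down	7	1e-06		malaria resistance; Cooley's anemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	HBB	141900	rs63750953	ctgggcataa	aa	-	gtcagggcag	5	8	down	9	1e-06		malaria resistance; Cooley's anemia; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T2	ACKR1	613665	rs2814778	ttggctctta	t	c	cttggaagca	10	12	down	4	0.001		malaria resistance; low white-blood-cell count; autoimmune diseases with hypergammaglobulinemia (hypothetical)
T3	StAR	600617	rs16887226	cagccttcag	c	t	gggggacatt	10	10	eq	0	0.5	EMSA implicates a non-TBP site	hypertension in diabetes; low endotoxin resistance (hypothetical)
T3	StAR	600617	rs544850971	tcagcggggg	a	g	catttaagac	10	12	down	5	0.01	printed alpha 1e-2 disagrees with the ladder value for Z=5 (1e-6); sole ladder exception	hypertension in diabetes; low endotoxin resistance (hypothetical)
T3	APOA1	107680	APOA1:-35A>C	tgcagacata	a	c	ataggccctg	3	4	down	5	1e-06	unregistered variant; printed flank3 'Ataggccctg' lowercased	hematuria; fatty liver; obesity; atherosclerosis-related autoimmune diseases (hypothetical)
T3	F3	134390	rs563763767	ccctttatag	c	t	gcgcggggca	3	2	up	6	1e-06		myocardial infarction; thrombosis; Hughes-syndrome thrombosis (hypothetical)
T3	TNFRSF18	603905	rs111426889	gtgctataaa	c	t	gccgccccct	4	2	up	8	1e-06		resistance to parasites; autoimmune diseases (hypothetical)
T3	NOS2	163730	NOS2:-51T>C	gtataaatac	t	c	tcttggctgc	2	1	up	3	0.01	unregistered variant	resistance to malaria or epilepsy; pemphigus vulgaris complications (hypothetical)
T3	MBL2	154545	rs72661131	tctatttcta	t	c	atagcctgca	2	4	down	12	1e-06		variable immunodeficiency; preeclampsia; stroke; preterm delivery in diabetic pregnancy (hypothetical)
T3	MBL2	154545	rs562962093	atctatttct	a	g	tatagcctgc	2	5	down	15	1e-06		preterm delivery in diabetic pregnancy; cardiovascular events in rheumatoid arthritis (hypothetical)
T3	MBL2	154545	rs567653539	tttctatata	g	a	cctgcaccca	2	1	up	12	1e-06		cardiovascular events in rheumatoid arthritis (hypothetical)
T3	DHFR	126060	rs10168	ctgcacaaat	a	g	gggacgaggg	15	9	up	9	1e-06		resistance to methotrexate treatment of leukemia and autoimmune diseases
T3	SOD1	147450	rs7277748	ggtctggcct	a	g	taaagtagtc	2	7	down	17	1e-06	the running text cites this row as rs1143627: known typo, the table's rs7277748 is kept	amyotrophic lateral sclerosis
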