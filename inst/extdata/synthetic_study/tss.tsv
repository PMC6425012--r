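chrom	tss	strand	gene_id	symbol	biotype
chr2	16670	-	G0001	GENE1	protein_coding
chr1	14007	-	G0002	GENE2	protein_coding
chr2	24279	-	G0003	GENE3	protein_coding
chr2	6969	+	G0004	GENE4	protein_coding
chr1	18786	+	G0005	GENE5	protein_coding
chr1	1365	+	G0006	GENE6	protein_coding
chr1	18892	+	G0007	GENE7	protein_coding
chr1	15481	+	G0008	GENE8	lincRNA
chr1	24203	-	G0009	GENE9	protein_coding
chr2	22545	-	G0010	GENE10	protein_coding
chr1	2432	+	G0011	GENE11	protein_coding
chr2	27250	+	G0012	GENE12	protein_coding
chr1	7966	+	G0013	GENE13	protein_coding
chr1	10322	-	G0014	GENE14	protein_coding
chr2	24504	+	G0015	GENE15	lincRNA
chr2	10932	-	G0016	GENE16	protein_coding
chr1	24450	-	G0017	GENE17	protein_coding
chr2	2683	+	G0018	GENE18	protein_coding
chr2	12538	-	G0001	GENE1	protein_coding
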