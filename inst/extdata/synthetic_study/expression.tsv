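gene_id	symbol	fpkm
G0001	GENE1	3.61
G0002	GENE2	0.96
G0003	GENE3	2.63
G0004	GENE4	23.8
G0005	GENE5	12.64
G0006	GENE6	14.26
G0007	GENE7	2.69
G0008	GENE8	15.89
G0009	GENE9	10.3
G0010	GENE10	3.4
G0011	GENE11	10.68
G0012	GENE12	0.95
G0013	GENE13	2.42
G0014	GENE14	1.8
G0015	GENE15	1.16
G0016	GENE16	1.12
G0017	GENE17	2.59
G0018	GENE18	3.31
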