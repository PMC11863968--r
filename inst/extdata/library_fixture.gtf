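chrF	crisprtrie	gene	1001	4000	.	+	.	gene_id "geneA";
chrF	crisprtrie	exon	1001	4000	.	+	.	gene_id "geneA";
chrF	crisprtrie	CDS	1001	4000	.	+	.	gene_id "geneA";
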