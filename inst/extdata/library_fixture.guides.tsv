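seqnames	start	end	strand	spacer	pam
chrF	1100	1120	+	CAGTTTCTTACGTGAGGAAT	CGG
chrF	4500	4520	+	ACGAAAGCCGATGGGTTATG	CGG
chrF	1580	1600	+	GTGTCGCGTAGACTCGGTCG	CGG
chrF	1820	1840	+	CTCCTCCCAAGACTATCTTC	CGG
chrF	2060	2080	+	CAGGCCGGCGCGCATGCGGC	CGG
chrF	2300	2320	+	ACCGTCAAAAGTGGATGAAC	CGG
chrF	2540	2560	+	TAGGTCTTAGAATACTACCC	CGG
chrF	2780	2800	+	CCTAGCTATAGCGGCAGCTC	CGG
chrF	3020	3040	+	GGTGTAATGCCCGCGGGACA	CGG
chrF	3260	3280	+	TCAAGCTGATGCCACGATCG	CGG
chrF	3500	3520	+	TTCAGGTCTCACTACCGTAT	CGG
chrF	3740	3760	+	CTAAATTTGCACTACTGTGT	CGG
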