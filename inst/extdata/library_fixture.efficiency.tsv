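spacer	efficiency
CAGTTTCTTACGTGAGGAAT	0.8
ACGAAAGCCGATGGGTTATG	0.8
GTGTCGCGTAGACTCGGTCG	0.1
CTCCTCCCAAGACTATCTTC	0.8
CAGGCCGGCGCGCATGCGGC	0.8
ACCGTCAAAAGTGGATGAAC	0.8
TAGGTCTTAGAATACTACCC	0.8
CCTAGCTATAGCGGCAGCTC	0.8
GGTGTAATGCCCGCGGGACA	0.8
TCAAGCTGATGCCACGATCG	0.8
TTCAGGTCTCACTACCGTAT	0.8
CTAAATTTGCACTACTGTGT	0.8
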