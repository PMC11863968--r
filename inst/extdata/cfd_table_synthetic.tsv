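record_type	position	rna_base	dna_base	pam	penalty
mismatch	1	A	C		0.908
mismatch	1	A	G		0.988
mismatch	1	A	T		0.908
mismatch	1	C	A		0.908
mismatch	1	C	G		0.908
mismatch	1	C	T		0.988
mismatch	1	G	A		0.988
mismatch	1	G	C		0.908
mismatch	1	G	T		0.908
mismatch	1	T	A		0.908
mismatch	1	T	C		0.988
mismatch	1	T	G		0.908
mismatch	2	A	C		0.866
mismatch	2	A	G		0.946
mismatch	2	A	T		0.866
mismatch	2	C	A		0.866
mismatch	2	C	G		0.866
mismatch	2	C	T		0.946
mismatch	2	G	A		0.946
mismatch	2	G	C		0.866
mismatch	2	G	T		0.866
mismatch	2	T	A		0.866
mismatch	2	T	C		0.946
mismatch	2	T	G		0.866
mismatch	3	A	C		0.824
mismatch	3	A	G		0.904
mismatch	3	A	T		0.824
mismatch	3	C	A		0.824
mismatch	3	C	G		0.824
mismatch	3	C	T		0.904
mismatch	3	G	A		0.904
mismatch	3	G	C		0.824
mismatch	3	G	T		0.824
mismatch	3	T	A		0.824
mismatch	3	T	C		0.904
mismatch	3	T	G		0.824
mismatch	4	A	C		0.782
mismatch	4	A	G		0.862
mismatch	4	A	T		0.782
mismatch	4	C	A		0.782
mismatch	4	C	G		0.782
mismatch	4	C	T		0.862
mismatch	4	G	A		0.862
mismatch	4	G	C		0.782
mismatch	4	G	T		0.782
mismatch	4	T	A		0.782
mismatch	4	T	C		0.862
mismatch	4	T	G		0.782
mismatch	5	A	C		0.74
mismatch	5	A	G		0.82
mismatch	5	A	T		0.74
mismatch	5	C	A		0.74
mismatch	5	C	G		0.74
mismatch	5	C	T		0.82
mismatch	5	G	A		0.82
mismatch	5	G	C		0.74
mismatch	5	G	T		0.74
mismatch	5	T	A		0.74
mismatch	5	T	C		0.82
mismatch	5	T	G		0.74
mismatch	6	A	C		0.698
mismatch	6	A	G		0.778
mismatch	6	A	T		0.698
mismatch	6	C	A		0.698
mismatch	6	C	G		0.698
mismatch	6	C	T		0.778
mismatch	6	G	A		0.778
mismatch	6	G	C		0.698
mismatch	6	G	T		0.698
mismatch	6	T	A		0.698
mismatch	6	T	C		0.778
mismatch	6	T	G		0.698
mismatch	7	A	C		0.656
mismatch	7	A	G		0.736
mismatch	7	A	T		0.656
mismatch	7	C	A		0.656
mismatch	7	C	G		0.656
mismatch	7	C	T		0.736
mismatch	7	G	A		0.736
mismatch	7	G	C		0.656
mismatch	7	G	T		0.656
mismatch	7	T	A		0.656
mismatch	7	T	C		0.736
mismatch	7	T	G		0.656
mismatch	8	A	C		0.614
mismatch	8	A	G		0.694
mismatch	8	A	T		0.614
mismatch	8	C	A		0.614
mismatch	8	C	G		0.614
mismatch	8	C	T		0.694
mismatch	8	G	A		0.694
mismatch	8	G	C		0.614
mismatch	8	G	T		0.614
mismatch	8	T	A		0.614
mismatch	8	T	C		0.694
mismatch	8	T	G		0.614
mismatch	9	A	C		0.572
mismatch	9	A	G		0.652
mismatch	9	A	T		0.572
mismatch	9	C	A		0.572
mismatch	9	C	G		0.572
mismatch	9	C	T		0.652
mismatch	9	G	A		0.652
mismatch	9	G	C		0.572
mismatch	9	G	T		0.572
mismatch	9	T	A		0.572
mismatch	9	T	C		0.652
mismatch	9	T	G		0.572
mismatch	10	A	C		0.53
mismatch	10	A	G		0.61
mismatch	10	A	T		0.53
mismatch	10	C	A		0.53
mismatch	10	C	G		0.53
mismatch	10	C	T		0.61
mismatch	10	G	A		0.61
mismatch	10	G	C		0.53
mismatch	10	G	T		0.53
mismatch	10	T	A		0.53
mismatch	10	T	C		0.61
mismatch	10	T	G		0.53
mismatch	11	A	C		0.488
mismatch	11	A	G		0.568
mismatch	11	A	T		0.488
mismatch	11	C	A		0.488
mismatch	11	C	G		0.488
mismatch	11	C	T		0.568
mismatch	11	G	A		0.568
mismatch	11	G	C		0.488
mismatch	11	G	T		0.488
mismatch	11	T	A		0.488
mismatch	11	T	C		0.568
mismatch	11	T	G		0.488
mismatch	12	A	C		0.446
mismatch	12	A	G		0.526
mismatch	12	A	T		0.446
mismatch	12	C	A		0.446
mismatch	12	C	G		0.446
mismatch	12	C	T		0.526
mismatch	12	G	A		0.526
mismatch	12	G	C		0.446
mismatch	12	G	T		0.446
mismatch	12	T	A		0.446
mismatch	12	T	C		0.526
mismatch	12	T	G		0.446
mismatch	13	A	C		0.404
mismatch	13	A	G		0.484
mismatch	13	A	T		0.404
mismatch	13	C	A		0.404
mismatch	13	C	G		0.404
mismatch	13	C	T		0.484
mismatch	13	G	A		0.484
mismatch	13	G	C		0.404
mismatch	13	G	T		0.404
mismatch	13	T	A		0.404
mismatch	13	T	C		0.484
mismatch	13	T	G		0.404
mismatch	14	A	C		0.362
mismatch	14	A	G		0.442
mismatch	14	A	T		0.362
mismatch	14	C	A		0.362
mismatch	14	C	G		0.362
mismatch	14	C	T		0.442
mismatch	14	G	A		0.442
mismatch	14	G	C		0.362
mismatch	14	G	T		0.362
mismatch	14	T	A		0.362
mismatch	14	T	C		0.442
mismatch	14	T	G		0.362
mismatch	15	A	C		0.32
mismatch	15	A	G		0.4
mismatch	15	A	T		0.32
mismatch	15	C	A		0.32
mismatch	15	C	G		0.32
mismatch	15	C	T		0.4
mismatch	15	G	A		0.4
mismatch	15	G	C		0.32
mismatch	15	G	T		0.32
mismatch	15	T	A		0.32
mismatch	15	T	C		0.4
mismatch	15	T	G		0.32
mismatch	16	A	C		0.278
mismatch	16	A	G		0.358
mismatch	16	A	T		0.278
mismatch	16	C	A		0.278
mismatch	16	C	G		0.278
mismatch	16	C	T		0.358
mismatch	16	G	A		0.358
mismatch	16	G	C		0.278
mismatch	16	G	T		0.278
mismatch	16	T	A		0.278
mismatch	16	T	C		0.358
mismatch	16	T	G		0.278
mismatch	17	A	C		0.236
mismatch	17	A	G		0.316
mismatch	17	A	T		0.236
mismatch	17	C	A		0.236
mismatch	17	C	G		0.236
mismatch	17	C	T		0.316
mismatch	17	G	A		0.316
mismatch	17	G	C		0.236
mismatch	17	G	T		0.236
mismatch	17	T	A		0.236
mismatch	17	T	C		0.316
mismatch	17	T	G		0.236
mismatch	18	A	C		0.194
mismatch	18	A	G		0.274
mismatch	18	A	T		0.194
mismatch	18	C	A		0.194
mismatch	18	C	G		0.194
mismatch	18	C	T		0.274
mismatch	18	G	A		0.274
mismatch	18	G	C		0.194
mismatch	18	G	T		0.194
mismatch	18	T	A		0.194
mismatch	18	T	C		0.274
mismatch	18	T	G		0.194
mismatch	19	A	C		0.152
mismatch	19	A	G		0.232
mismatch	19	A	T		0.152
mismatch	19	C	A		0.152
mismatch	19	C	G		0.152
mismatch	19	C	T		0.232
mismatch	19	G	A		0.232
mismatch	19	G	C		0.152
mismatch	19	G	T		0.152
mismatch	19	T	A		0.152
mismatch	19	T	C		0.232
mismatch	19	T	G		0.152
mismatch	20	A	C		0.11
mismatch	20	A	G		0.19
mismatch	20	A	T		0.11
mismatch	20	C	A		0.11
mismatch	20	C	G		0.11
mismatch	20	C	T		0.19
mismatch	20	G	A		0.19
mismatch	20	G	C		0.11
mismatch	20	G	T		0.11
mismatch	20	T	A		0.11
mismatch	20	T	C		0.19
mismatch	20	T	G		0.11
pam	NA			AAA	0
pam	NA			AAC	0
pam	NA			AAG	0.25
pam	NA			AAT	0
pam	NA			ACA	0
pam	NA			ACC	0
pam	NA			ACG	0.03
pam	NA			ACT	0
pam	NA			AGA	0.07
pam	NA			AGC	0
pam	NA			AGG	1
pam	NA			AGT	0
pam	NA			ATA	0
pam	NA			ATC	0
pam	NA			ATG	0
pam	NA			ATT	0
pam	NA			CAA	0
pam	NA			CAC	0
pam	NA			CAG	0.25
pam	NA			CAT	0
pam	NA			CCA	0
pam	NA			CCC	0
pam	NA			CCG	0.03
pam	NA			CCT	0
pam	NA			CGA	0.07
pam	NA			CGC	0
pam	NA			CGG	1
pam	NA			CGT	0
pam	NA			CTA	0
pam	NA			CTC	0
pam	NA			CTG	0
pam	NA			CTT	0
pam	NA			GAA	0
pam	NA			GAC	0
pam	NA			GAG	0.25
pam	NA			GAT	0
pam	NA			GCA	0
pam	NA			GCC	0
pam	NA			GCG	0.03
pam	NA			GCT	0
pam	NA			GGA	0.07
pam	NA			GGC	0
pam	NA			GGG	1
pam	NA			GGT	0
pam	NA			GTA	0
pam	NA			GTC	0
pam	NA			GTG	0
pam	NA			GTT	0
pam	NA			TAA	0
pam	NA			TAC	0
pam	NA			TAG	0.25
pam	NA			TAT	0
pam	NA			TCA	0
pam	NA			TCC	0
pam	NA			TCG	0.03
pam	NA			TCT	0
pam	NA			TGA	0.07
pam	NA			TGC	0
pam	NA			TGG	1
pam	NA			TGT	0
pam	NA			TTA	0
pam	NA			TTC	0
pam	NA			TTG	0
pam	NA			TTT	0
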