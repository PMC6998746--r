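specimen_id	gene	first_exon	last_exon	copy_state	replications	note
S1	CDH1	4	9	het_del	3
S2	BRCA2	*	*	dup	3
S3	BRCA1	*	*	het_del	3
S4	TP53	*	*	het_del	3
S5	BRCA1	16	17	het_del	3
S6	BRCA1	1	2	dup	3
S7	BRCA1	9	12	het_del	3
S8	BRCA1	21	23	het_del	5
S9	BRCA1	13	13	dup	3
S10	BRCA1	9	12	het_del	5
S11	MLH1	16	19	het_del	1
S12	PMS2	*	*	het_del	1	exon 11-15 CNV status not assayed by sequencing
S13	MLH1	16	19	het_del	1
S14	PMS2	8	8	het_del	1
S15	CDH1	*	*	dup	1
S16	BRCA1	1	22	dup	1
S17	PALB2	9	10	het_del	1
S18	BRCA1	22	22	het_del	1
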