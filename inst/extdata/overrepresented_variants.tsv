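Chr	Start	End	Ref	Alt	Gene.refGene	Func.refGene	ExonicFunc.refGene	gnomAD_genome_ALL	gnomAD_exome_ALL	SIFT_pred	Polyphen2_HVAR_pred	CADD_phred	fathmm-MKL_coding_pred	n_samples_carrying	mode
11	59282861	59282861	A	G	OR4D9	exonic	nonsynonymous SNV	0.0329	0.0359	D	D	21	N	20	dominant
4	27019495	27019495	C	T	STIM2	exonic	nonsynonymous SNV	.	0.0001	T	B	14.31	D	1	recessive
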