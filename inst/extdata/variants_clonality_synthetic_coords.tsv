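#oncohistone-screen v0.1.0
# Published diagnosis/remission VAFs; coordinates and read counts are synthetic placeholders
sample_id	gene	protein_change	chrom	pos	ref	alt	alt_reads	depth	vaf
105	HIST1H3H	K27M	chr6	27777801	A	T			0.532
083	HIST1H3A	Q69H	chr6	26031651	G	T			0.422
105R	HIST1H3H	K27M	chr6	27777801	A	T			0.434
083R	HIST1H3A	Q69H	chr6	26031651	G	T			0.545
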