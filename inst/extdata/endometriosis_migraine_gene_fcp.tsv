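gene	chrom	gene_p_endometriosis	gene_p_migraine	fcp_published
ARL14EP	11	1.00e-06	5.54e-02	9.81e-07
TRIM32	9	2.76e-02	5.00e-06	2.32e-06
SLC35G6	17	1.59e-03	9.40e-05	2.50e-06
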