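species	singletons	pairs	triplets	clusters	cluster_genes	total_nlrs
C. argyrosperma	20	2	1	0	0	27
C. maxima	24	7	1	2	12	53
C. moschata	20	5	2	9	51	87
C. pepo	32	3	1	0	0	41
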