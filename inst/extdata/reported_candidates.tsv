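id	round	rank	enrichment	sequence	z_score	cluster_size
A1	R5	1	26	TTATCGTACGACAGTCATCCTACAC	10.75	14
A3	R5	3	22	CACAGTGCGTCACATTTAGGGCATT	-7.06	46
B10	R4	10	14	CAGTGCGTGCTTATTGGCGTAGCGTC	-2.08	18
D3	R2	3	12	ATGGTCGCAAGAACTGAGAATTTAC	1.6	10
L1	R0	1	1	CCGTCTTCTGCTTGAAAAAAAAAAA	-15.9	NA
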