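round	fraction	reads_millions	duplication_percent
R0	free	6.7	11.8
R1	bound	3.8	13.0
R2+	bound	2.7	14.0
R2-	bound	8.4	12.4
R3+	bound	6.4	14.0
R3-	bound	5.3	20.0
R3-	free	6.2	14.0
R4	bound	8.0	24.1
R5	bound	10.1	37.7
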