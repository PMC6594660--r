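##gff-version 3
ctg1	toy	gene	21	30	.	+	.	ID=geneA
ctg1	toy	gene	41	50	.	-	.	ID=geneB
ctg1	toy	gene	6	15	.	+	.	ID=geneC
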