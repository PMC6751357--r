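gene	n_exons	mutation_exon	cdna_length	strand
ghrb	7	7	1650	+
mia3	27	4	5667	+
mki67	16	9	6750	-
mlf1	7	3	813	+
plg	20	4	2451	+
rnf126	11	11	1063	+
wdr1	18	6	1674	-
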