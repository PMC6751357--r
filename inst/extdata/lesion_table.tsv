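gene	kind	carrier_start	carrier_end	sequence	variant_pop
ghrb	insertion	1423	1425	TGT	Surface
mia3	insertion	2013	2018	GATGCC	Surface
mki67	insertion	1957	1992	CCCAAAACCCCTTCACCATCCTCATGCCCAGCAATG	Surface
mki67	deletion	2154	2156	TTG	Surface
mlf1	insertion	247	258	ATGGACAACATC	Surface
plg	insertion	290	290	T	Surface
plg	deletion	294	294	C	Surface
rnf126	deletion	1046	1050	AGTTC	Surface
wdr1	insertion	626	631	TGAGAT	Tinaja
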