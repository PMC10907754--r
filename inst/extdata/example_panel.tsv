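# umi_length=12
# anchor_seq=CGATGTACGCTA
# min_reads_per_umi=3
name	gene	contig	start	end	amplicon
TP53_B	TP53	chr17	7675100	7675180	GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCCATGCTTAATT
TP53_F	TP53	chr17	7675900	7675980	GCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCTGTTGATTTAAAAAAAATCAC
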