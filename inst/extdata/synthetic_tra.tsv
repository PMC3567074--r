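gene_id	role	start	end	rank
synth_tra_seed42	exon	0	198	1
synth_tra_seed42	female_intron_1	198	2698	NA
synth_tra_seed42	male_exon	278	509	NA
synth_tra_seed42	exon	2698	2848	2
synth_tra_seed42	intron	2848	2920	2
synth_tra_seed42	exon	2920	3082	3
synth_tra_seed42	intron	3082	3151	3
synth_tra_seed42	exon	3151	3397	4
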