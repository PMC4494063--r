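species	chr1_bp	chr2_bp	chr3_bp	gc_percent	n_genes	protein_coding_nonredundant	protein_coding_incl_duplicates	rrna	trna	snrna	introns
Amorphochlora_amoebiformis	131920	124024	118014	30.0	340	295	300	18	21	3	793
Lotharella_vacuolata	166173	141647	124056	24.7	359	294	319	18	19	3	1028
Bigelowiella_natans	140598	134144	98137	28.5	332	288	288	18	22	3	865
Lotharella_oceanica	210000	207543	194115	33.0	636	338	596	18	19	3	1021
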