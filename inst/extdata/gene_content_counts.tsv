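quantity	count
shared_protein_coding_genes_4_chlorarachniophytes	189
shared_function_predicted_genes	171
shared_orfans	18
total_function_predicted_genes	198
chlorarachniophyte_core_genes	171
core_genes_shared_with_cryptophytes	93
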