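item	count
ohnolog_genes_HR	477
ohnolog_genes_LR	103
pairs_HR_HR	187
pairs_LR_HR	103
pairs_LR_LR	0
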