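snp	gene
snp001	IL6
snp013	APOE
snp140	AKT1
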