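chr19	55236713	55367367	KIR
chr6	32549334	32709302	HLA
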