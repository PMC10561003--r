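genus	fwd_name	rev_name	fwd	rev	product_bp
Bacillus	F	R	GTCTGTAACTGACGCTGAGGC	GCGATTACTAGCGATTCCA	626
Acinetobacter	F2	R2	ATGTGAAATCCCCGAGCTT	AGTTTGTCACTGGCAGTATCCT	536
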