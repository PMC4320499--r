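kind	scope_type	chrom	start	end	band_from	band_to	gene	zygosity
monosomy	whole_chromosome	X						heterozygous
monosomy	whole_chromosome	9						heterozygous
translocation_amplification	gene	11					CCND1	unspecified
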