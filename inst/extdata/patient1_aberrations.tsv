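kind	scope_type	chrom	start	end	band_from	band_to	gene	zygosity
monosomy	whole_chromosome	13						heterozygous
copy_loss	cytoband_range	17			p13.1	p13.1		homozygous
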