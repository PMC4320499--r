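kind	scope_type	chrom	start	end	band_from	band_to	gene	zygosity
copy_gain	gene	11					CCND1	heterozygous
copy_loss	gene	17					TP53	heterozygous
monosomy	whole_chromosome	13						heterozygous
copy_gain	gene	7					IL6	heterozygous
copy_gain	gene	9					JAK2	heterozygous
copy_gain	gene	19					JAK3	heterozygous
copy_gain	gene	7					SHH	heterozygous
copy_gain	gene	7					SMO	heterozygous
copy_gain	gene	15					DLL4	heterozygous
copy_gain	gene	9					NOTCH1	heterozygous
copy_gain	gene	7					MET	heterozygous
copy_gain	gene	15					IGF1R	heterozygous
copy_gain	gene	8					FGFR1	heterozygous
copy_gain	gene	1					MCL1	heterozygous
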