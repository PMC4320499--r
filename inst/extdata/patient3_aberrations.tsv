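kind	scope_type	chrom	start	end	band_from	band_to	gene	zygosity
copy_loss	karyotype	del(7)(q22q36)						unspecified
translocation_amplification	gene	11					AIP	unspecified
translocation_amplification	gene	11					PDEA2	unspecified
translocation_amplification	gene	14					TCL1A	unspecified
translocation_amplification	gene	11					RCE1	unspecified
translocation_amplification	gene	11					CCND1	unspecified
translocation_amplification	gene	11					MAP4K2	unspecified
translocation_amplification	gene	11					MAP3K11	unspecified
translocation_amplification	gene	14					AKT1	unspecified
translocation_amplification	gene	14					YY1	unspecified
translocation_amplification	gene	11					FOSL1	unspecified
translocation_amplification	gene	11					FGF19	unspecified
translocation_amplification	gene	11					IL18BP	unspecified
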