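name	class	targets	actions	ec50	hill
BEZ235	small_molecule	PI3K;mTORC1	inhibit	1	1
ABT-199	small_molecule	BCL2	inhibit	1	1
sirolimus	small_molecule	mTORC1	inhibit	1	1
trametinib	small_molecule	MEK	inhibit	1	1
bortezomib	small_molecule	proteasome	inhibit	1	1
tofacitinib	small_molecule	JAK2;JAK3	inhibit	1	1
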