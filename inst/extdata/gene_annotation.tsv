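gene	chrom	start	end	cytoband
TP53	17	7668402	7687550	17p13.1
STAT3	17	42313324	42388568	17q21.2
RB1	13	48303748	48481890	13q14.2
FOXO1	13	40555668	40666641	13q14.11
BRCA2	13	32315474	32400266	13q13.1
RXRA	9	136345895	136459411	9q34.2
TGFBR1	9	99104038	99154192	9q22.33
TJP2	9	69124355	69255208	9q21.11
TSC1	9	132891349	132945370	9q34.13
JAK2	9	4984390	5129948	9p24.1
NOTCH1	9	136494433	136546048	9q34.3
XIAP	X	123859708	123913972	Xq25
CAV1	7	116524785	116561185	7q31.2
BRAF	7	140719327	140924929	7q34
CUX1	7	101817560	102180744	7q22.1
EZH2	7	148807374	148884344	7q36.1
MET	7	116672390	116798377	7q31.2
NRF1	7	129611720	129757082	7q32.2
SMO	7	129188633	129213545	7q32.1
CUL1	7	148697914	148801110	7q36.1
RHEB	7	151466012	151519924	7q36.1
SHH	7	155799980	155812463	7q36.3
IL6	7	22725442	22732002	7p15.3
AIP	11	67483041	67491103	11q13.2
PDEA2	11	67000000	67040000	11q13.2
RCE1	11	66842156	66846381	11q13.1
CCND1	11	69641156	69654474	11q13.3
MAP4K2	11	64788080	64810394	11q13.1
MAP3K11	11	65594622	65611200	11q13.1
FOSL1	11	65892049	65900520	11q13.1
FGF19	11	69698079	69704642	11q13.3
IL18BP	11	71708632	71714588	11q13.4
BIRC3	11	102317450	102339403	11q22.2
TCL1A	14	95709735	95714033	14q32.13
AKT1	14	104769349	104795751	14q32.33
YY1	14	100238298	100282788	14q32.2
DLL4	15	40929339	40939151	15q15.1
IGF1R	15	98648539	98964530	15q26.3
JAK3	19	17824780	17848071	19p13.11
MCL1	1	150579979	150601162	1q21.3
FGFR1	8	38411138	38468834	8p11.23
CTNNB1	3	41194741	41260096	3p22.1
BCL2	18	63123346	63320128	18q21.33
PTEN	10	87863113	87971930	10q23.31
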