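chrom	band
1	p36
1	q21
1	q25
3	p22
3	q21
7	p22
7	p15
7	p11
7	q11
7	q21
7	q22
7	q31
7	q32
7	q34
7	q36
8	p23
8	p11
8	q24
9	p24
9	p21
9	p13
9	q21
9	q22
9	q34
10	p15
10	q23
11	p15
11	q13
11	q14
11	q22
13	q12
13	q13
13	q14
13	q21
14	q11
14	q32
15	q15
15	q26
17	p13
17	p12
17	q21
18	q21
19	p13
19	q13
X	p22
X	q25
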