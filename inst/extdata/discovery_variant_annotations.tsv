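variant_key	gene	consequence	sift	polyphen	lrt	mutation_taster	fathmm	phylop_class	gerp	aa_change
3:100467:G:T	IGSF10	missense	D	D	D	N	D	C	5.18	p.Arg156Leu
3:100481:G:A	IGSF10	missense	D	D	D	D	T	C	4.94	p.Glu161Lys
3:106791:A:G	IGSF10	missense	D	P	N	D	T	C	3.71	p.Glu2264Gly
3:107840:G:A	IGSF10	missense	D	D	D	D	T	C	5.24	p.Asp2614Asn
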