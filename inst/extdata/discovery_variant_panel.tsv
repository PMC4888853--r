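variant_key	aa_change	exon	cohort_af	control_af	maf_fin	maf_eur	maf_all
3:100467:G:T	p.Arg156Leu	3	0.028	0	0	0.005	0.004
3:100481:G:A	p.Glu161Lys	3	0.056	0.005	0.020	0.007	0.010
3:106791:A:G	p.Glu2264Gly	6	0.005	0
3:107840:G:A	p.Asp2614Asn	6	0.033	0	0	0.008	0.008
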