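chrom	slaf_number	all_snp	polymorphic_slaf	polymorphic_snp
1H	22762	20349	6768	7708
2H	35479	25365	7495	8660
3H	32596	37540	12767	14690
4H	31198	19263	5703	6404
5H	31635	23457	6740	7750
6H	28518	31182	10605	11648
7H	32883	38521	12755	14594
unknown	18630	20045	5144	6088
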