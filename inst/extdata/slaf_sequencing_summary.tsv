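sample	total_reads	gc_pct	q30_pct	slaf_number	total_depth
parent_dom	17631146	42.81	92.2	160977	2646465
parent_rec	38025068	43.41	93.3	181313	4916562
bulk_dom	63431978	43.20	93.4	216958	9852375
bulk_rec	61740302	42.98	92.8	205768	8492938
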