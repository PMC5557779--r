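marker	Y225	Y314	Y333	Y372	Y401	Y406	Y316	Y415	Y328	Y330	Y331	Y332	Y379	Y422	Y444
HZSNP63	0/1	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
HZSNP34	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
HZSNP36	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
HZSNP32	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
HZSNP59	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
HZSNP61	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1
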