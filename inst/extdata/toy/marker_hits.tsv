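scaffold_id	marker_id	orf_id	evalue	bitscore
S01	polB	o01	1e-30	110
S01	polB	o03	1e-12	50
S01	mcp	o01	1e-20	75
S01	vltf3	o03	1e-18	70
S03	polB	o06	1e-25	95
S03	polB	o07	1e-08	33
S03	mcp	o06	1e-15	60
S07	a32	o10	1e-40	140
S07	mcp	o10	1e-22	80
S07	vltf3	o11	1e-16	62
S09	polB	o13	1e-10	42
S12	mcp	o16	1e-35	120
S12	mcp	o17	1e-06	28
S12	polB	o17	1e-14	55
S12	vltf3	o18	1e-03	15
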