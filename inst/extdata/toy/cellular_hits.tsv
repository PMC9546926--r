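o03	sub01	34.9	120	70	2	1	120	1	120	1e-20	80.0	Bacteria
o03	sub02	35.0	100	65	1	1	100	1	100	1e-05	35.0	Bacteria
o05	sub03	90.0	80	8	0	1	80	1	80	1e-04	60.0	Bacteria
o05	sub04	50.0	80	40	1	1	80	1	80	1e-10	70.0	Eukaryota
o07	sub05	40.0	150	90	3	1	150	1	150	1e-08	55.0	Archaea
o07	sub06	45.0	140	77	2	1	140	1	140	1e-09	58.0	Bacteria
o11	sub07	38.0	70	43	1	1	70	1	70	1e-06	40.0	Eukaryota
o12	sub08	99.0	90	1	0	1	90	1	90	1e-30	120.0	Viruses
o15	sub09	55.0	75	34	0	1	75	1	75	1e-12	66.0	Bacteria
o18	sub10	35.0	55	36	1	1	55	1	55	1e-05	33.0	Bacteria
o20	sub11	36.0	64	41	0	1	64	1	64	2e-05	32.0	Bacteria
o20	sub12	70.0	64	19	0	1	64	1	64	1e-07	50.0	Eukaryota
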