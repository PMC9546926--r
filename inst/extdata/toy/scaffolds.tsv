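scaffold_id	length
S01	15000
S02	12000
S03	20000
S04	9000
S05	10000
S06	8000
S07	25000
S08	11000
S09	30000
S10	9999
S11	14000
S12	50000
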