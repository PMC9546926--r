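scaffold_id	sample_id	covered_length
S01	sampleA	12000
S02	sampleA	10000
S03	sampleA	10001
S07	sampleA	9000
S12	sampleA	45000
S01	sampleB	11000
S09	sampleB	5000
S12	sampleB	30000
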