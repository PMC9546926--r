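Synthetic hand-written toy fixture: 12 scaffolds with small ORF, profile-hit,
cellular-hit, marker-hit and coverage tables whose per-filter survivor counts
were computed by hand while authoring the files and frozen in manifest.json.
Not derived from any real dataset.
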