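{
  "n_orfs_total": 20,
  "n_orfs_ge_50aa": 16,
  "n_profile_rows_input": 10,
  "n_profile_rows_kept": 7,
  "n_viral_orfs": 6,
  "n_cellular_rows_input": 12,
  "n_cellular_rows_kept": 8,
  "n_scaffolds_ge_10kb": 9,
  "n_marker_rows_input": 15,
  "n_marker_rows_ranked": 14,
  "n_selected_marker_hits": 10,
  "n_high_confidence": 2,
  "n_extended": 4,
  "n_presence_calls": 5
}
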