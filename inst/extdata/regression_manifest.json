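{
  "seed": 1,
  "n_probes_expressed": 2169,
  "n_de_selected": 1097,
  "cluster_sizes": [42, 44, 85, 90, 94, 95, 98, 98, 100, 101, 107, 143],
  "n_markers_hc": 30,
  "marker_fraction_confirmed": 1,
  "marker_mean_fold": 13.5453,
  "n_hc_enriched": 189,
  "motif_full": {
    "N": 4999,
    "K": 421,
    "n": 189,
    "k": 81
  },
  "motif_full_p": 1.35146e-39,
  "motif_full_ef": 5.0889,
  "motif_narrowed_p": 1.55266e-65,
  "motif_narrowed_ef": 12.0677,
  "position_mode_start": -75,
  "n_putative_targets": 73,
  "chip_bound_any": 62,
  "chip_bound_both": 29,
  "cross_species_p": 1.17623e-19,
  "cross_species_ef": 3.77853,
  "shift_p": 9.34095e-32,
  "shift_median_difference": 0.785942,
  "top_kmer": "ATGGCAAC",
  "top_kmer_p_adjusted": 4.44576e-35,
  "panel_p": 1.12256e-05,
  "panel_k": 28
}
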