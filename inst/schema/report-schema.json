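{
  "pipeline": "string",
  "seed": "number",
  "thresholds": {
    "fpkm_min": "number",
    "de_log2fc": "number",
    "fdr": "number",
    "rho_min": "number",
    "peak_fold": "number",
    "flank": "number",
    "psi_min_total": "number"
  },
  "n_samples": "number",
  "events": {
    "total": "number",
    "per_type": "object",
    "se_ri_percent": "number"
  },
  "expression": {
    "n_expressed": "number",
    "n_deg": "number"
  },
  "splicing": {
    "n_tested": "number",
    "n_das": "number",
    "n_das_increased": "number",
    "n_das_decreased": "number"
  },
  "deg_dasg": {
    "n_deg": "number",
    "n_dasg": "number",
    "n_intersect": "number"
  },
  "methylation": {
    "n_peaks": "number",
    "n_dm_peaks": "number"
  },
  "integration": {
    "n_sedmas": "number",
    "quadrants": {
      "increased_hyper": "number",
      "increased_hypo": "number",
      "decreased_hyper": "number",
      "decreased_hypo": "number"
    }
  },
  "network": {
    "n_tested": "number",
    "n_edges": "number"
  }
}
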