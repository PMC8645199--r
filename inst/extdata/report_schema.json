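{
  "description": "Structural schema of the decoupling analysis report: for each top-level block that is present, the listed member fields are required.",
  "required_if_present": {
    "approach1_mantel": ["r", "p", "n_permutations"],
    "approach2_null": ["min", "max", "ci95", "n_pairs"],
    "approach2_pic_grid": ["trait_a", "trait_b", "r", "p", "df"],
    "approach2_pls": ["r", "p"],
    "approach3_overall": ["r", "p", "df"],
    "approach3_windows": ["start", "end", "n_branches", "r", "p", "low_n"],
    "approach3_ess": ["oral", "lpj"],
    "approach3_max_rate": ["oral", "lpj"]
  }
}
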