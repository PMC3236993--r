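{
  "notes": ["Baseline two-strategy ACL model configuration.", "counts_*: pooled per-class patient counts from the four-study evidence table; normalized to distributions at load time.", "residual_cost_*: additive per-arm calibration constants = published arm cost minus literal rollback (16038 - 15653.5496, 15466 - 15293.1342); set to 0 for a literal rollback.", "utilities: per-class means calibrated with fit_utilities so arm-level expected effects hit the published arm cost / cost-effectiveness ratios (16038/20612, 15466/23391); the underlying expert-survey key is unpublished. SDs are package defaults, not elicited values: 0.10 capped at (1 - mean)/3.5 so the [0,1] ceiling stays >= 3.5 sigma away and truncation of the normal draws is negligible; see the methods vignette."],
  "model": {
    "p_fail": 0.035,
    "p_crossover": 0.16,
    "p_seq_operative": 0.34,
    "p_seq_conservative": 0.77,
    "split_oa_operative": 0.86,
    "split_oa_conservative": 0.74,
    "cost_surgical": 9926,
    "cost_conservative": 2535,
    "cost_oa": 17361,
    "cost_meniscus": 6382,
    "residual_cost_operative": 384.4504,
    "residual_cost_conservative": 172.8658,
    "counts_operative": {
      "I": 12,
      "II": 24,
      "III": 31,
      "IV": 98,
      "V": 64
    },
    "counts_conservative": {
      "I": 23,
      "II": 23,
      "III": 32,
      "IV": 38,
      "V": 39
    },
    "sequelae_class": "II",
    "horizon_months": 90
  },
  "utilities": {
    "I": {
      "mean": 0.32104934,
      "sd": 0.1
    },
    "II": {
      "mean": 0.62592444,
      "sd": 0.1
    },
    "III": {
      "mean": 0.80669195,
      "sd": 0.0552
    },
    "IV": {
      "mean": 0.92891947,
      "sd": 0.0203
    },
    "V": {
      "mean": 0.97162957,
      "sd": 0.0081
    }
  },
  "psa": {
    "n_iterations": 10000,
    "seed": 1,
    "wtp_max": 100000,
    "wtp_step": 1000
  }
}
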