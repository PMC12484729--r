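{
  "seed": 1,
  "level": "district",
  "rounds": ["2016", "2021"],
  "sim": {
    "n_states": 6,
    "districts_per_state": 4,
    "clusters_per_district": 6,
    "individuals_per_cluster": 20,
    "beta0": [-0.4, -0.6],
    "sigma2_f": 0.2,
    "sigma2_v": 0.1,
    "sigma2_u": 0.3,
    "weight_dispersion": 0.25,
    "national_projected_pop": 114273000
  },
  "mcmc": {
    "burn_in": 300,
    "chain_length": 1800
  },
  "displacement": 0.2,
  "indicator": {
    "id": "indicator_1",
    "label": "Synthetic demonstration indicator",
    "category": "Synthetic",
    "direction": "lower_is_better"
  }
}
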