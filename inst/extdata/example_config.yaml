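# Example run configuration for run_sret_study() / read_sret_config().
# Omitted fields keep their package defaults.
seed: 1
design:
  n_participants: 33
  words_per_valence: 26
  n_blocks: 3
  n_sessions: 2
  hue_aware_rate: 0.26
truth:
  v_mean:
    "positive:blue_depleted": -0.73
    "positive:blue_enriched": -0.71
    "negative:blue_depleted": 1.13
    "negative:blue_enriched": 1.36
  v_sd_between: 0.25
  a_mean: 1.42
  a_sd: 0.20
  z_mean: 0.49
  z_sd: 0.04
  t_mean: 0.46
  t_sd: 0.05
mcmc:
  n_samples: 6000
  burn_in: 1000
  thin: 5
  n_chains: 3
variants: ["v", "null"]
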