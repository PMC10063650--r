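# One simulation scenario for `wstabsel.R simulate` / read_scenario_config().
# Note: quote the sample-size key, YAML 1.1 would otherwise read bare `n` as
# a boolean.
"n": 200
p: 50
p_signal: 5
beta_dist: [0.5, 1.5]
prevalence: 0.5
cov_structure: toeplitz
toeplitz_rho: 0.9
seed: 1
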