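# A small experiment grid for `wstabsel.R experiment`: one scenario, two
# methods, two replicates. Scale up replicates/methods for a real study.
scenario:
  "n": 200
  p: 50
  p_signal: 5
  beta_dist: [0.5, 1.5]
  prevalence: 0.5
  cov_structure: toeplitz
  toeplitz_rho: 0.9
  seed: 1
methods:
  - method: wss
    B: 20
    alpha: 1.0
  - method: cpss
    B: 20
    pfer_bound: 1
    pi_thr: 0.6
    assumption: r_concave
replicates: 2
seed: 7
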