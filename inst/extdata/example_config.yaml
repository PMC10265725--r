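# Example pipeline configuration (see ?run_config and ?cohort_config).
# Simulates a small two-site cohort with a conditioned thalamic FA deficit
# and runs the full analysis with 50 null networks per scan.
out_dir: runs/example
n_null: 50
groupings: [injury, symptom_parent]
metric_names: [Cp, Lp, sigma, Eg, NCp]
rci_threshold: 1.645
rci_reference: all
fdr_alpha_injury: 0.05
fdr_alpha_symptom: 0.025
seed: 1
cohort:
  n_tbi: 60
  n_oi: 30
  sites: [S1, S2]
  site_additive: [-0.02, 0.02]
  site_multiplicative: [0.98, 1.02]
  noise_sd_edge: 0.02
  seed: 1
  effect_spec:
    - target_regions: [THA.L, THA.R]
      direction: -1
      magnitude: 0.06
      group: [TBI]
      sex: [F]
      day_min: 150
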