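# Demo configuration for run_pipeline() / inst/scripts/run_pipeline.R.
# Small sizes for a quick run; thresholds default to the standard values
# (MAG quality >90%/<5% and >50%/<10%; Mash 0.05/0.15/0.30; presence
# 1e-5 in >=3 samples; ARG identity >=90 with >=80 mutual coverage).
seed: 1
strains:
  hosts: [cat, dog, human]
  n_per_host: 8
  L: 1000
  t_w: 0.01
  t_b: 0.09
  kappa: 2
  mixing: 0
  min_sites: 100
community:
  n_per_host: 8
  n_taxa: 30
  n_signature: 3
  effect: 2
  axes: 2
  frequency_correct: true
permanova:
  permutations: 999
screening: {}
arg: {}
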