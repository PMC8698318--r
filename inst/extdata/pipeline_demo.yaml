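# Demo configuration for run_pipeline(): simulate all inputs, then run every
# stage. Entries override pipeline_config() defaults per stage.
out_dir: results/pipeline_demo
seed: 42
phases:
  n_permutations: 199
  sig_level: 0.05
  min_segment: 3
isotopes:
  natural_abundance: 0.0107
regulons:
  r_threshold: 0.8
  alpha: 0.1
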