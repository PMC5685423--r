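# Example pipeline configuration: overrides are merged over
# default_config(); everything not listed keeps its default.
observer:
  strategy: super_resolution
  motion_knowledge: estimated
  noise_sd: 4
experiment:
  n_subjects: 4
  n_runs: 5
fit:
  n_boot: 500
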