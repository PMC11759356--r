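# Small synthetic demo study for run_pipeline()
seed: 1
network: brain
simulate:
  TR: 2
  run_duration: 270
  condition: Pain
  n_FM: 3
  n_HC: 3
  n_runs: 2
  noise_sd: 0.2
subregions:
  n_subregions: 2
  divergence: 0.3
  search: false
  n_starts: 1
fit:
  n_restarts: 2
null_sim:
  reps: 30
features:
  n_masked: 3
pupil:
  enabled: true
  n_FM: 6
  n_HC: 4
  task_duration: 40
  fs: 50
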