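# Reduced-scale demonstration configuration: three group presets with the
# study's connectivity distributions but small cohorts, resting-state and
# statistics stages only.
tr: 2.6
fd_threshold: 0.5
band: [0.01, 0.08]
n_keep: 250
hrf:
  delta: 2.25
  tau: 1.25
  exponent: 2
seed: 7
stages: [rsfc, stats]
presets:
  meditator:
    n_subjects: 4
    r_mean: -0.55
    r_sd: 0.18
  inlab:
    n_subjects: 4
    r_mean: -0.41
    r_sd: 0.21
  hcp:
    n_subjects: 4
    r_mean: -0.39
    r_sd: 0.19
    n_runs: 4
    n_timepoints: 346
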