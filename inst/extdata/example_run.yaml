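# Example end-to-end run: simulated two-group serum cohort.
design:
  groups: {control: 25, case: 25}
  effects:
    citrate:       {case: 1.5}
    phenylalanine: {case: 1.5}
    formate:       {case: 1.5}
  shift_jitter_sd: 0.003
  noise_sd: 0.01
  baseline_amplitude: 0.05
  intensity_cv: 0.15
  seed: 101
contrasts:
  - [case, control]
k: 7
n_perm: 200
alpha: 0.05
pca_a: 2
seed: 101
processing:
  lb_hz: 1
  bin_width: 0.004
  bin_range: [0.5, 9.0]
  water_region: [4.23, 5.18]
  align_regions:
    - [1.43, 1.50]
    - [6.98, 7.10]
    - [7.70, 7.84]
  reference_ppm: 5.236
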