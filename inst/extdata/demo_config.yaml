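# Demo run: all four synthetic assays over the four built-in genotype
# presets, sized to complete in a few minutes on one CPU.
seed: 20240101
output_dir: results/demo
genotypes: [DmCRY, AeCRY1, AgCRY1, cry_null]
assays: [locomotor, ephys, choice, icc, stats]
locomotor:
  n_flies: 8
  days_ld: 4
  days_dd: 5
  lux: 400
  grid_min_h: 16.0
  grid_max_h: 32.0
  grid_step_h: 0.1
  min_power: 20
  min_width_h: 2
  alpha: 0.05
  anticipation_days: 3
ephys:
  n_cells: 2
  sampling_hz: 2000
  pre_dark_s: 50
  stim_s: 5
  post_s: 95
  n_sweeps: 5
  wavelength_nm: 450
  intensity_uw_cm2: 200
  baseline_window_s: 10
  gaussian_sigma_ms: 50
  butter_order: 3
  butter_cutoff_hz: 2
  evoked_output_hz: 10
choice:
  n_flies: 20
  minutes: 30
  wavelength_nm: 450
  intensity_uw_cm2: 10
  window_min: 30
icc:
  n_brains: 3
  neurons_per_brain: 4
  zts: [5, 11, 17, 23]
  channel: TIM
stats:
  q: 0.1
  tail: greater
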