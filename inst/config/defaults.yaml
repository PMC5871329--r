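# Single source of truth for the analysis defaults.
# All times are ms relative to cue onset unless noted.
task:
  values: [0, 1, 2, 4, 8]          # drops of juice
  fixation_ms: 2000
  cue_ms: 1000
  delay_ms: 1500
  perturbation_onset_ms: 200
  perturbation_duration_ms: 100
simulate:
  n_blocks: 9
  n_positive: 5
  n_negative: 3
  n_untuned: 3
  n_nonvisual: 4
  p_incomplete: 0.0
  include_pupil: true
analysis:
  alpha: 0.05
  fdr_q: 0.05
  baseline_window: [-200, 0]
  selectivity_window: [150, 550]
  model_window: [200, 1000]
  psth_bin_step_ms: 10
  psth_window_ms: 50
  modulation_min_duration_ms: 200
  modulation_period: [200, 1000]
  uniform_window: [450, 750]       # supplementary fixed-window variant
  pupil_baseline_window: [400, 900]  # ms after fixation acquisition
  pupil_response_dur_ms: 1000
  min_norm_divisor: 0.1            # spikes/s
  first_block_n: 50
fit:
  n_starts: 16
  b_bounds: [-2, 2]
  c_bounds: [0, 100]
  d_bounds: [0, 2]
seeds:
  simulate: 1
  split: 2
  balance: 3
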