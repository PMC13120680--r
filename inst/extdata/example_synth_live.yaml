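# Example live run on a synthetic time lapse: one cadherin channel whose ring
# amplitude rises to a peak and declines, a CAAX-like reference channel, and
# known inter-channel pixel shifts that the registration step must undo.
mode: synth-live
seed: 1
output_dir: streakquant_live_out
synth:
  image_shape: [160, 160]
  n_cells: 20
  nucleus_radius_range: [5, 7]
  membrane_ring_radius: 12
  membrane_ring_width: 3
  background_level: 20
  noise_sd: 2
  cytoplasm_level: 60
  channels:
    ncad: {role: membrane_marker, weights: [1.0], means: [100], sds: [0]}
    caax: {role: caax,            weights: [1.0], means: [150], sds: [0]}
live:
  n_positions: 3
  n_timepoints: 12
  max_shift: 6
  shifts:
    caax: [0, 0]
    ncad: [3, -2]
  trajectory:
    ncad: [30, 45, 60, 80, 100, 120, 135, 120, 100, 80, 60, 45]
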