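# Example fixed-cell run on synthetic fields: two differentiation conditions,
# mixture fate-marker populations, quadrant gating and per-image statistics.
# Quantification defaults are the standard directional-profiling settings:
# 6 rays, 25-px window, top 20% of samples per ray.
mode: synth-fixed
seed: 1
output_dir: streakquant_out
synth:
  image_shape: [192, 192]
  n_cells: 40
  n_images: 4
  nucleus_radius_range: [6, 9]
  membrane_ring_radius: 14
  membrane_ring_width: 3
  background_level: 10
  noise_sd: 2
  channels:
    dapi:  {role: dapi,           weights: [1.0], means: [400], sds: [15]}
    sox17: {role: nuclear_marker, weights: [0.7, 0.3], means: [300, 40], sds: [25, 10]}
    foxa2: {role: nuclear_marker, weights: [0.7, 0.3], means: [280, 35], sds: [25, 10]}
    ecad:  {role: membrane_marker, weights: [1.0], means: [120], sds: [20]}
  shared_population_channels: [sox17, foxa2]
conditions:
  DE: {}
  control:
    channels:
      sox17: {role: nuclear_marker, weights: [0.1, 0.9], means: [300, 40], sds: [25, 10]}
      foxa2: {role: nuclear_marker, weights: [0.1, 0.9], means: [280, 35], sds: [25, 10]}
quant:
  n_directions: 6
  ray_length: 25
  top_fraction: 0.2
  sample_step: 1
  ray_origin: centroid
  normalize_to_dapi: true
segmentation:
  use: truth        # or "fallback" for the intensity-based segmenter
  min_area: 50
gates:
  - {channel_x: sox17_dapi_norm, channel_y: foxa2_dapi_norm,
     threshold_x: 0.35, threshold_y: 0.35}
comparisons:
  - [DE, control]
n_comparisons: 1
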