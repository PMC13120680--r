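# Fixture builders used across test files. All fixtures are generated in
# code; nothing is read from disk.

# standard fixed-cell channel set: DAPI, two co-regulated nuclear fate
# markers with a 70/30 two-population mixture, one cadherin membrane channel
test_channels_fixed <- function(marker_weights = c(0.7, 0.3),
                                membrane_mean = 100, membrane_sd = 20) {
  list(
    dapi = channel_spec("dapi", population_model(1, 400, 15)),
    sox17 = channel_spec("nuclear_marker",
                         population_model(marker_weights, c(300, 40), c(25, 10))),
    foxa2 = channel_spec("nuclear_marker",
                         population_model(marker_weights, c(280, 35), c(25, 10))),
    ecad = channel_spec("membrane_marker",
                        population_model(1, membrane_mean, membrane_sd))
  )
}

# isolated-cell geometry: neighbouring membranes stay outside the 25-px
# profiling window, so the generator's amplitude is the operator's truth
test_field_isolated <- function(seed, n_cells = 50, noise_sd = 10,
                                membrane_sd = 25) {
  field_spec(
    image_shape = c(512, 512), n_cells = n_cells,
    nucleus_radius_range = c(6, 9),
    membrane_ring_radius = 15, membrane_ring_width = 5,
    background_level = 10, noise_sd = noise_sd,
    channel_specs = test_channels_fixed(membrane_sd = membrane_sd),
    min_spacing = 45,
    shared_population_channels = c("sox17", "foxa2"),
    seed = seed
  )
}

# compact confluent field for fast structural tests
test_field_small <- function(seed, n_cells = 15, noise_sd = 2, ...) {
  field_spec(
    image_shape = c(160, 160), n_cells = n_cells,
    nucleus_radius_range = c(5, 7),
    membrane_ring_radius = 12, membrane_ring_width = 3,
    background_level = 10, noise_sd = noise_sd,
    channel_specs = test_channels_fixed(),
    shared_population_channels = c("sox17", "foxa2"),
    seed = seed, ...
  )
}

# live-imaging field: non-overlapping cells so the designed ring/cytoplasm
# ratio is exactly the expected per-image readout
test_field_live <- function(seed, n_cells = 20, noise_sd = 2,
                            image_shape = c(224, 224)) {
  field_spec(
    image_shape = image_shape, n_cells = n_cells,
    nucleus_radius_range = c(5, 7),
    membrane_ring_radius = 12, membrane_ring_width = 3,
    background_level = 20, noise_sd = noise_sd, cytoplasm_level = 60,
    min_spacing = 28,
    channel_specs = list(
      ncad = channel_spec("membrane_marker", population_model(1, 100, 0)),
      caax = channel_spec("caax", population_model(1, 150, 0))
    ),
    seed = seed
  )
}

# a single-cell, noise-free field with a known annulus amplitude
test_field_one_cell <- function(amplitude = 50, background = 0, seed = 1) {
  field_spec(
    image_shape = c(64, 64), n_cells = 1,
    nucleus_radius_range = c(6, 6),
    membrane_ring_radius = 15, membrane_ring_width = 3,
    background_level = background, noise_sd = 0,
    channel_specs = list(
      dapi = channel_spec("dapi", population_model(1, 400, 0)),
      ecad = channel_spec("membrane_marker", population_model(1, amplitude, 0))
    ),
    seed = seed
  )
}

# constant-intensity image + centred disk mask, built directly (not via the
# generator) for identity checks
test_constant_image <- function(value = 7, H = 64, W = 64, radius = 6) {
  px <- array(value, c(H, W, 3))
  img <- multichannel_image(px, c(dapi = "dapi", marker = "nuclear_marker",
                                  ecad = "membrane_marker"))
  d <- sqrt(outer((seq_len(H) - H / 2)^2, (seq_len(W) - W / 2)^2, `+`))
  mask <- label_mask(matrix(as.integer(d <= radius), H, W), "nuclear")
  list(image = img, mask = mask)
}

# minimal synth-fixed pipeline config (as a list, mirroring the YAML schema)
test_pipeline_config <- function(out_dir, seed = 1) {
  list(
    mode = "synth-fixed", seed = seed, output_dir = out_dir,
    synth = list(
      image_shape = c(160L, 160L), n_cells = 15L, n_images = 2L,
      nucleus_radius_range = c(5, 7), membrane_ring_radius = 12,
      membrane_ring_width = 3, background_level = 10, noise_sd = 2,
      channels = list(
        dapi = list(role = "dapi", weights = 1, means = 400, sds = 15),
        sox17 = list(role = "nuclear_marker", weights = c(0.7, 0.3),
                     means = c(300, 40), sds = c(25, 10)),
        foxa2 = list(role = "nuclear_marker", weights = c(0.7, 0.3),
                     means = c(280, 35), sds = c(25, 10)),
        ecad = list(role = "membrane_marker", weights = 1, means = 120,
                    sds = 20)
      ),
      shared_population_channels = c("sox17", "foxa2")
    ),
    conditions = list(
      DE = list(),
      control = list(channels = list(
        sox17 = list(role = "nuclear_marker", weights = c(0.1, 0.9),
                     means = c(300, 40), sds = c(25, 10)),
        foxa2 = list(role = "nuclear_marker", weights = c(0.1, 0.9),
                     means = c(280, 35), sds = c(25, 10))
      ))
    ),
    quant = list(n_directions = 6L, ray_length = 25, top_fraction = 0.2),
    segmentation = list(use = "truth"),
    gates = list(list(channel_x = "sox17_dapi_norm",
                      channel_y = "foxa2_dapi_norm",
                      threshold_x = 0.35, threshold_y = 0.35)),
    comparisons = list(c("DE", "control")),
    n_comparisons = 1L
  )
}
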