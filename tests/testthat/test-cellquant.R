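# Fixed-cell quantification: nuclear means, DAPI normalization, and the
# directional membrane-profiling operator with its invariants.

test_that("nuclear means follow the arithmetic definition", {
  cst <- test_constant_image(value = 7)
  m <- nuclear_mean_intensity(get_channel(cst$image, "marker"), cst$mask)
  expect_equal(unname(m), 7)

  # one 4-pixel cell with values 1..4
  ch <- matrix(0, 10, 10); ch[3:4, 3:4] <- c(1, 2, 3, 4)
  lab <- matrix(0L, 10, 10); lab[3:4, 3:4] <- 1L
  expect_equal(unname(nuclear_mean_intensity(ch, label_mask(lab, "nuclear"))),
               2.5)

  # empty mask: empty result; shape mismatch: error
  expect_length(nuclear_mean_intensity(ch, label_mask(matrix(0L, 10, 10),
                                                      "nuclear")), 0)
  expect_error(nuclear_mean_intensity(ch, label_mask(matrix(0L, 5, 5),
                                                     "nuclear")), "shape")
})

test_that("nuclear mean estimates sit within sampling error of the truth", {
  # noise_sd = 2 per pixel; a nucleus of area A estimates the true level with
  # SE 2/sqrt(A); check 3-SE coverage >= 95% over many cells
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    f <- generate_fixed_field(test_field_small(seed = 300 + s, n_cells = 20))
    rec <- quantify_cells(f$image, f$mask, quant_config(), "i")
    truth <- f$truth$cells
    se <- 2 / sqrt(rec$nucleus_area)
    err <- abs(rec$sox17_nuclear_mean - (truth$sox17_true_intensity + 10))
    hits <- hits + sum(err <= 3 * se)
    total <- total + nrow(rec)
  }
  expect_gte(hits / total, 0.95)
})

test_that("DAPI normalization is a per-cell ratio with scale invariance", {
  rec <- data.frame(cell_id = 1:3,
                    dapi_nuclear_mean = c(4, 5, 0),
                    mk_nuclear_mean = c(12, 5, 7))
  expect_warning(out <- dapi_normalize(rec, "mk"), "nonpositive DAPI")
  expect_equal(out$mk_dapi_norm[1], 3.0)
  expect_equal(out$mk_dapi_norm[2], 1.0)  # identical channels give ratio 1
  expect_true(is.na(out$mk_dapi_norm[3]))
  expect_identical(out$qc_zero_dapi, c(FALSE, FALSE, TRUE))

  # scaling both channels by k leaves ratios unchanged
  rec2 <- rec[1:2, ]
  rec2$dapi_nuclear_mean <- rec2$dapi_nuclear_mean * 7.3
  rec2$mk_nuclear_mean <- rec2$mk_nuclear_mean * 7.3
  out2 <- dapi_normalize(rec2, "mk")
  expect_equal(out2$mk_dapi_norm, out$mk_dapi_norm[1:2])
})

test_that("directional profiling matches constants and the brute-force oracle", {
  cst <- test_constant_image(value = 11)
  dmi <- directional_membrane_intensity(get_channel(cst$image, "ecad"),
                                        cst$mask, quant_config())
  expect_equal(dmi$membrane_signal, 11)
  expect_true(all(abs(as.matrix(dmi[paste0("dir_", 1:6)]) - 11) < 1e-12))

  zero <- test_constant_image(value = 0)
  dmi0 <- directional_membrane_intensity(get_channel(zero$image, "ecad"),
                                         zero$mask, quant_config())
  expect_equal(dmi0$membrane_signal, 0)

  # single noise-free annulus cell: exact agreement with the enumerated oracle
  f <- generate_fixed_field(test_field_one_cell(amplitude = 50))
  ecad <- get_channel(f$image, "ecad")
  dmi1 <- directional_membrane_intensity(ecad, f$mask, quant_config())
  cen <- mask_centroids(f$mask)
  oracle <- oracle_directional_one(ecad, cen$centroid_row, cen$centroid_col)
  expect_equal(dmi1$membrane_signal, oracle$signal, tolerance = 1e-9)
  expect_equal(unlist(dmi1[paste0("dir_", 1:6)]), oracle$directions,
               tolerance = 1e-9, ignore_attr = TRUE)
  # the annulus dominates: well above the zero background (bilinear sampling
  # of the pixelated ring attenuates the nominal 50), and never above it
  expect_gt(dmi1$membrane_signal, 20)
  expect_lte(dmi1$membrane_signal, 50)
})

test_that("profiling is monotone under constant offsets and angle rotation", {
  f <- generate_fixed_field(test_field_small(seed = 51, n_cells = 10))
  ecad <- get_channel(f$image, "ecad")
  base <- directional_membrane_intensity(ecad, f$mask, quant_config())
  # adding b >= 0 raises every membrane signal by exactly b
  shifted <- directional_membrane_intensity(ecad + 12.5, f$mask, quant_config())
  expect_equal(shifted$membrane_signal, base$membrane_signal + 12.5,
               tolerance = 1e-9)

  # rotating the image 60 degrees about a symmetric cell's centroid moves the
  # signal by < 2% (bilinear interpolation error only)
  f1 <- generate_fixed_field(test_field_one_cell(amplitude = 80, background = 5))
  ecad1 <- get_channel(f1$image, "ecad")
  cen <- mask_centroids(f1$mask)
  rot <- oracle_rotate_about(ecad1, cen$centroid_row, cen$centroid_col,
                             pi / 3, fill = 5)
  s0 <- directional_membrane_intensity(ecad1, f1$mask, quant_config())
  s1 <- directional_membrane_intensity(rot, f1$mask, quant_config())
  expect_lt(abs(s1$membrane_signal - s0$membrane_signal) / s0$membrane_signal,
            0.02)
})

test_that("out-of-bounds ray samples are discarded, whole-OOB cells flagged", {
  # cell near the top-left corner: upward/leftward rays leave the image
  ch <- matrix(5, 40, 40)
  lab <- matrix(0L, 40, 40); lab[2:4, 2:4] <- 1L
  dmi <- directional_membrane_intensity(ch, label_mask(lab, "nuclear"),
                                        quant_config())
  expect_equal(dmi$membrane_signal, 5)  # retained samples are all constant

  # a mask larger than the image is rejected
  expect_error(directional_membrane_intensity(ch, label_mask(matrix(0L, 10, 10),
                                                             "nuclear"),
                                              quant_config()), "shape")
})

test_that("edge ray origin starts sampling outside the nucleus", {
  f <- generate_fixed_field(test_field_one_cell(amplitude = 60, background = 0))
  ecad <- get_channel(f$image, "ecad")
  # ring at radius 15, nucleus radius 6, a 10-px window: from the centroid the
  # window (1..10) misses the ring entirely; from the nuclear edge the window
  # (~7..16) covers it
  s_cen <- directional_membrane_intensity(ecad, f$mask,
                                          quant_config(ray_length = 10))
  s_edge <- directional_membrane_intensity(
    ecad, f$mask, quant_config(ray_length = 10, ray_origin = "edge"))
  expect_equal(s_cen$membrane_signal, 0)
  expect_gt(s_edge$membrane_signal, 40)
})

test_that("quantify_cells assembles a complete per-cell table", {
  f <- generate_fixed_field(test_field_small(seed = 61, n_cells = 8))
  rec <- quantify_cells(f$image, f$mask, quant_config(), image_id = "imgA")
  expect_identical(nrow(rec), 8L)
  expect_identical(unique(rec$image_id), "imgA")
  expect_true(all(c("dapi_nuclear_mean", "sox17_nuclear_mean",
                    "sox17_dapi_norm", "foxa2_dapi_norm", "ecad_membrane",
                    "ecad_dir_1", "ecad_dir_6") %in% names(rec)))
  expect_identical(sort(rec$cell_id), f$truth$cells$cell_id)
  # a z-stack is projected before quantification: duplicating the field as
  # two identical slices changes nothing
  px <- array(0, c(dim(f$image$pixels), 2))
  px[, , , 1] <- f$image$pixels
  px[, , , 2] <- f$image$pixels
  zimg <- multichannel_image(px, f$image$channel_roles)
  rec_z <- quantify_cells(zimg, f$mask, quant_config(), image_id = "imgA")
  expect_equal(rec_z, rec)
})

test_that("quant_config validates its parameters", {
  expect_error(quant_config(n_directions = 0), "n_directions")
  expect_error(quant_config(top_fraction = 0), "top_fraction")
  expect_error(quant_config(top_fraction = 1.2), "top_fraction")
  expect_error(quant_config(ray_length = 0), "ray_length")
})
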