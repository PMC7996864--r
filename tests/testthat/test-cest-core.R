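test_that("mtr_asym evaluates the defining formula on hand-built spectra", {
  sp <- z_spectrum(c(-1.4, 0, 1.4), c(0.80, 0.1, 0.70))
  expect_equal(mtr_asym(sp, 1.4), 0.10)
  expect_error(mtr_asym(sp, 2), "range")
})

test_that("sampled MTRasym matches the closed-form Lorentzian oracle", {
  pool <- pool_model(gag_amplitude = 0.03, mt_amplitude = 0.05)
  sp <- simulate_z_spectrum(pool, dense_offsets())
  for (dw in c(1.0, 1.25, 1.5)) {
    expect_lt(abs(mtr_asym(sp, dw) - pool_mtr_asym(pool, dw)), 1e-10)
  }
})

test_that("band averaging uses nominal sampled offsets in the GAG band", {
  # constant asymmetry of 0.02 across the band -> 2.0 %
  off <- dense_offsets()
  z <- rep(0.8, length(off))
  z[off > 0] <- 0.78
  sp <- z_spectrum(off, z)
  expect_equal(band_gagcest(sp), 2.0)
  expect_error(band_gagcest(sp, gag_band(0.9, 1.9)), NA)
  expect_error(
    band_gagcest(z_spectrum(c(-0.5, 0, 0.5), c(1, 0, 1))),
    "band"
  )
})

test_that("band gagCEST agrees with the quadrature of the closed form", {
  pool <- pool_model(gag_amplitude = 0.03)
  off <- acquisition_spec()$cest_offsets
  sp <- simulate_z_spectrum(pool, off)
  band_w <- off[off >= 0.9 & off <= 1.9]
  oracle <- 100 * mean(pool_mtr_asym(pool, band_w))
  expect_lt(abs(band_gagcest(sp) - oracle), 0.05)
  # the default sweep contributes exactly these six offsets
  expect_equal(band_w, c(0.9375, 1.125, 1.3125, 1.5, 1.6875, 1.875))
})

test_that("correct_spectrum is the identity at delta = 0 and restores shifts", {
  sp <- simulate_z_spectrum(default_pool(), dense_offsets(), b0_offset = 0.2)
  same <- correct_spectrum(sp, 0)
  expect_equal(same$z, sp$z)
  expect_false(any(same$extrapolated))

  corrected <- correct_spectrum(sp, 0.2)
  ref <- simulate_z_spectrum(default_pool(), dense_offsets())
  interior <- !corrected$extrapolated
  expect_lt(max(abs(corrected$z - ref$z)[interior]), 1e-3)
  expect_true(any(corrected$extrapolated))

  sym <- simulate_z_spectrum(pool_model(gag_amplitude = 0), dense_offsets())
  expect_lt(abs(band_gagcest(correct_spectrum(sym, 0))), 1e-3)
  expect_error(correct_spectrum(sp, NA_real_), "finite")
  expect_error(correct_spectrum(sp, 1.5), "1 ppm")
})

test_that("mirroring a spectrum about zero negates its asymmetry", {
  sp <- simulate_z_spectrum(default_pool(), dense_offsets())
  mirrored <- z_spectrum(sort(-sp$offset_ppm), rev(sp$z))
  dw <- c(1, 1.5, 1.75)
  expect_equal(mtr_asym(mirrored, dw), -mtr_asym(sp, dw), tolerance = 1e-12)
})

test_that("B0 correction then band averaging undoes a simulated shift", {
  for (b0 in c(-0.25, 0.1, 0.3)) {
    shifted <- simulate_z_spectrum(default_pool(), dense_offsets(0.125),
      b0_offset = b0
    )
    corrected <- correct_spectrum(shifted, b0)
    ref <- simulate_z_spectrum(default_pool(), dense_offsets(0.125))
    expect_lt(
      max(abs(corrected$z - ref$z)[!corrected$extrapolated]), 2e-3
    )
  }
})

test_that("gagcest maps recover phantom truth and respect validity", {
  ph <- noiseless_phantom()
  mask <- foreground_mask(ph$s0)
  b0 <- estimate_b0_map(ph$wassr, ph$wassr_offsets, ph$s0, mask)
  map <- gagcest_map(ph$cest, ph$cest_offsets, ph$s0, b0, mask)
  disk <- ph$truth$labels == 2 & map$valid
  expect_lt(max(abs(map$value - ph$truth$gagcest)[disk]), 0.1)
  expect_false(any(map$valid[!mask]))

  # gag-free phantom (flat field) maps to ~0 % inside disks
  scene0 <- phantom_scene(
    np_gag_amplitude = 0, af_gag_amplitude = 0, b0_field = "none"
  )
  ph0 <- generate_phantom(scene0, acquisition_spec(noise_sd = 0))
  map0 <- gagcest_map(ph0$cest, ph0$cest_offsets, ph0$s0,
    mask = ph0$truth$labels == 2
  )
  expect_lt(max(abs(map0$value[ph0$truth$labels == 2])), 0.05)
})

test_that("skipping B0 correction under a ramp inflates the map error", {
  ph <- noiseless_phantom()
  disk_mask <- ph$truth$labels == 2
  b0 <- estimate_b0_map(ph$wassr, ph$wassr_offsets, ph$s0, disk_mask)
  with_corr <- gagcest_map(ph$cest, ph$cest_offsets, ph$s0, b0, disk_mask)
  without <- gagcest_map(ph$cest, ph$cest_offsets, ph$s0, NULL, disk_mask)
  err_with <- mean(abs(with_corr$value - ph$truth$gagcest)[disk_mask])
  err_without <- mean(abs(without$value - ph$truth$gagcest)[disk_mask])
  expect_lt(err_with, err_without)
})

test_that("the pipeline is invariant to global intensity scaling", {
  ph <- noiseless_phantom()
  disk_mask <- ph$truth$labels == 2
  map1 <- gagcest_map(ph$cest, ph$cest_offsets, ph$s0, mask = disk_mask)
  map2 <- gagcest_map(ph$cest * 3, ph$cest_offsets, ph$s0 * 3,
    mask = disk_mask
  )
  expect_equal(map1$value, map2$value, tolerance = 1e-12)
})

test_that("roi_gagcest averages per partition and flags empty ROIs", {
  value <- matrix(1.7, 10, 10)
  map <- structure(
    list(value = value, valid = matrix(TRUE, 10, 10)),
    class = "gagcest_map"
  )
  pix <- as.matrix(expand.grid(row = 2:4, col = 2:6))
  disks <- tibble::tibble(
    level = "L1/2",
    pixels = list(pix),
    np_pixels = list(pix[1:5, , drop = FALSE]),
    af_pixels = list(pix[6:15, , drop = FALSE])
  )
  out <- roi_gagcest(map, disks)
  expect_equal(out$gagcest, rep(1.7, 3))
  expect_equal(out$n_pixels, c(15L, 5L, 10L))

  # fully invalid ROI is missing, not zero
  map$valid[] <- FALSE
  out2 <- roi_gagcest(map, disks)
  expect_true(all(is.na(out2$gagcest)))
  expect_equal(out2$n_pixels, rep(0L, 3))
})
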