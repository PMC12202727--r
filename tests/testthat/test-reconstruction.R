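test_that("Cartesian recon reproduces the rendered disk and behaves linearly", {
  g <- image_grid(64, 0.2)
  scn0 <- scene(particles(numeric(0), numeric(0)), noise_sigma = 0)
  sch <- cartesian_schedule(g, tr = 0.05, averages = 1)
  ks <- acquire(scn0, sch, seed = 1)
  img <- cartesian_recon(ks)
  inside <- disk_interior_mask(64, 0.2, scn0$cylinder_radius - 1.4)
  # interior uniform within 2% (the Gibbs ring extends ~7 voxels inward
  # from the disk edge at this matrix size and is excluded)
  expect_true(all(abs(img[inside] / 100 - 1) < 0.02))
  # impulse object: flat k-space with a linear phase -> PSF peak at x0
  ks_delta <- ks
  kx <- ((1:64) - 33) / 12.8
  ks_delta$data <- outer(exp(-2i * pi * kx * 1.3),
                         exp(-2i * pi * kx * -0.7))
  psf <- cartesian_recon(ks_delta)
  pk <- arrayInd(which.max(psf), c(64, 64))
  expect_equal(((pk[1] - 32.5) * 0.2), 1.3, tolerance = 0.11)
  expect_equal(((pk[2] - 32.5) * 0.2), -0.7, tolerance = 0.11)
  # linearity of the complex recon
  scn1 <- scene(particles(2, 1), noise_sigma = 0)
  k1 <- acquire(scn1, sch, seed = 1)
  mix <- ks
  mix$data <- 0.6 * ks$data + 1.7 * k1$data
  i_mix <- cartesian_recon(mix)
  i0 <- cartesian_recon(ks, magnitude = FALSE)
  i1 <- cartesian_recon(k1, magnitude = FALSE)
  expect_equal(as.vector(unclass(i_mix)), as.vector(Mod(0.6 * i0 + 1.7 * i1)),
               tolerance = 1e-10)
  # missing lines error
  ks_na <- ks
  ks_na$data[, 5] <- NA
  expect_error(cartesian_recon(ks_na), "missing")
})

test_that("zero-filling enhancement min-projects fine samples onto the native grid", {
  fx <- cached_fixture("static_ref", seed = 5)
  # factor 1 is the identity
  expect_equal(as.vector(unclass(zero_fill_enhance(fx$kspace, 1))),
               as.vector(unclass(cartesian_recon(fx$kspace))))
  expect_error(zero_fill_enhance(fx$kspace, 1.5), "integer")
  # noiseless void centered between voxels: enhancement must deepen it
  g <- image_grid(64, 0.2)
  scn <- scene(particles(2.0, 1.0, void_amplitude = 0.24),
               noise_sigma = 0)
  sch <- cartesian_schedule(g, tr = 0.05, averages = 1)
  ks <- acquire(scn, sch, seed = 1)
  native <- cartesian_recon(ks)
  enh <- zero_fill_enhance(ks, 4)
  msk <- object_mask(scn, g)
  tb <- tibble::tibble(id = 1, x = 2.0, y = 1.0)
  sl_nat <- measure_spots(native, tb, mask = msk)$sl
  sl_enh <- measure_spots(enh, tb, mask = msk)$sl
  expect_gte(sl_enh, sl_nat)
  # seeded noisy phantom: enhancement deepens the void minima on average
  # (its SL gain additionally depends on each void's sub-voxel alignment)
  m0 <- measure_fixture(fx, cartesian_recon(fx$kspace), 0)
  m1 <- measure_fixture(fx, zero_fill_enhance(fx$kspace, 4), 0)
  expect_lt(mean(m1$min), mean(m0$min))
})

test_that("density compensation implements the ramp filter with gradient-ramp correction", {
  g2 <- image_grid(64, 0.2)
  # no ramp portion: pure ramp filter |k|^(d-1)
  sch2 <- radial_schedule(g2, n_spokes = 10, samples_per_spoke = 40, f = 2,
                          ramp_fraction = 0, dual_echo = FALSE)
  w2 <- density_compensation(sch2)
  body <- 5:39   # away from DC floor and endpoint differences
  expect_equal(w2[body] / w2[body[1]],
               sch2$kmag[body] / sch2$kmag[body[1]], tolerance = 0.02)
  g3 <- image_grid(32, 0.35, dim = 3)
  sch3 <- radial_schedule(g3, n_spokes = 10, samples_per_spoke = 40, f = 2,
                          ramp_fraction = 0, dual_echo = FALSE)
  w3 <- density_compensation(sch3)
  expect_equal(w3[body] / w3[body[1]],
               (sch3$kmag[body] / sch3$kmag[body[1]])^2, tolerance = 0.03)
  # on the gradient ramp the weight is additionally scaled by d|k|/ds
  schr <- radial_schedule(g2, n_spokes = 10, samples_per_spoke = 40, f = 2,
                          ramp_fraction = 0.5, dual_echo = FALSE)
  wr <- density_compensation(schr)
  dk <- c(schr$kmag[2] - schr$kmag[1],
          (schr$kmag[3:40] - schr$kmag[1:38]) / 2,
          schr$kmag[40] - schr$kmag[39])
  expect_equal(wr[10:30] / wr[30], (schr$kmag * dk)[10:30] / (schr$kmag * dk)[30],
               tolerance = 1e-9)
  expect_gt(wr[1], 0)  # DC floor
  expect_error(density_compensation(
    radial_schedule(g2, n_spokes = 2, f = 1, dual_echo = FALSE), 0), "n_spokes_used")
})

test_that("density-compensated gridding matches the rendering oracle; unweighted gridding does not", {
  g <- image_grid(64, 0.2)
  scn0 <- scene(particles(numeric(0), numeric(0)), noise_sigma = 0)
  sch <- radial_schedule(g, n_spokes = 240, f = 4, dual_echo = FALSE)
  ks <- acquire(scn0, sch, seed = 1)
  ref <- render_image(scn0, 0, g)
  inside <- disk_interior_mask(64, 0.2, scn0$cylinder_radius - 0.6)
  img <- grid_recon(ks, echo = 1)
  expect_lt(nrmse_to(img[inside], ref[inside]), 0.05)
  # flat weights: reconstruction fails the oracle badly
  coords <- voidlapse:::radial_grid_coords(sch, 1:240)
  y <- as.vector(ks$data[, , 1])
  w_flat <- rep(mean(density_compensation(sch, 240)), length(y))
  img_flat <- Mod(voidlapse:::nufft_adjoint(y, coords, w_flat, g$n, g$dx))
  img_flat <- img_flat / mean(img_flat[inside]) * 100
  expect_gt(nrmse_to(as.vector(img_flat), as.vector(unclass(ref))), 0.15)
  expect_lt(nrmse_to(as.vector(unclass(img)), as.vector(unclass(ref))), 0.15)
  expect_error(grid_recon(ks, interleaves = integer(0)), "empty")
})

test_that("3D gridded recon locates static voids at ground truth", {
  fx <- cached_fixture("radial_static", seed = 1)
  img <- grid_recon(fx$kspace, echo = 1)
  m <- measure_fixture(fx, img, 0)
  truth <- truth_spots(fx$scene, 0)
  # void centers within 0.5 voxel (0.175 mm) of ground truth + half-voxel
  # rounding of the reported voxel-center coordinates
  err <- sqrt((m$x - truth$x)^2 + (m$y - truth$y)^2 + (m$z - truth$z)^2)
  expect_true(all(err <= sqrt(3) * 0.35))
  expect_true(all(m$cnr > 2))
})

test_that("empty object reconstructs to (numerically) zero", {
  g <- image_grid(32, 0.4)
  scn <- scene(particles(numeric(0), numeric(0)), background_signal = 0,
               noise_sigma = 0)
  sch <- radial_schedule(g, n_spokes = 60, f = 3, dual_echo = FALSE)
  img <- grid_recon(acquire(scn, sch, seed = 1), echo = 1)
  expect_lt(max(img), 1e-8)
})

test_that("echo combination follows its closed forms and beats sum-of-squares on deep echo-2 voids", {
  i <- matrix(runif(16, 1, 5), 4)
  # p = -0.5: (sqrt(I1) + sqrt(I2))^2; equal inputs -> 4 I
  expect_equal(combine_echoes(i, i, p = -0.5), 4 * i, tolerance = 1e-12)
  expect_equal(combine_echoes(matrix(4), matrix(0), p = -0.5), matrix(4))
  expect_equal(combine_echoes(matrix(1), matrix(1), p = 1), matrix(sqrt(2)))
  expect_equal(combine_echoes(i, 4 * i, p = -0.5), (sqrt(i) + sqrt(4 * i))^2)
  expect_error(combine_echoes(i, i, p = -1), "p = -1")
  expect_error(combine_echoes(-i, i), "non-negative")
  # sum of squares
  expect_equal(sos_combine(matrix(1), matrix(1)), matrix(sqrt(2)))
  expect_equal(sos_combine(i, 0 * i), i)
  # dual-echo phantom: weighted combination yields a deeper relative void
  # than SOS when the echo-2 void is deeper
  fx <- cached_fixture("radial_static", seed = 1)
  i1 <- Mod(grid_recon(fx$kspace, echo = 1, magnitude = FALSE))
  i2 <- Mod(grid_recon(fx$kspace, echo = 2, magnitude = FALSE))
  msk <- object_mask(fx$scene, fx$schedule$grid)
  tb <- truth_spots(fx$scene, 0)
  wc <- combine_echoes(i1, i2)
  attr(wc, "dx") <- 0.35
  ss <- sos_combine(i1, i2)
  attr(ss, "dx") <- 0.35
  sl_wc <- measure_spots(wc, tb, mask = msk)$sl
  sl_ss <- measure_spots(ss, tb, mask = msk)$sl
  expect_gt(mean(sl_wc), mean(sl_ss))
})

test_that("inverted maximum intensity projections map voids to bright spots", {
  v <- array(10, c(8, 8, 8))
  expect_true(all(mip_render(v)$z == 0))
  v[3, 5, 6] <- 2   # one void
  mp <- mip_render(v)
  expect_equal(arrayInd(which.max(mp$z), c(8, 8)), matrix(c(3, 5), 1))
  expect_equal(max(mp$z), 8)
  # two voids along x: one spot in the x-projection, two elsewhere
  v2 <- array(10, c(8, 8, 8))
  v2[2, 4, 4] <- 1
  v2[7, 4, 4] <- 1
  mp2 <- mip_render(v2)
  expect_equal(sum(mp2$x > 5), 1)   # projection along x merges them
  expect_equal(sum(mp2$z > 5), 2)
  expect_equal(sum(mp2$y > 5), 2)
  expect_error(mip_render(matrix(1, 4, 4)), "3D")
})
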