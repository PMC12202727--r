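test_that("spoke directions cover the sphere uniformly and in balance", {
  d1 <- generate_spoke_directions(1)
  expect_equal(sum(d1^2), 1)
  d <- generate_spoke_directions(1000)
  expect_equal(rowSums(d^2), rep(1, 1000), tolerance = 1e-12)
  # deterministic
  expect_identical(d, generate_spoke_directions(1000))
  # nearest-neighbor angular spacing: coefficient of variation < 0.5
  # (brute-force pairwise angles)
  gram <- pmin(pmax(d %*% t(d), -1), 1)
  diag(gram) <- -1
  nn <- acos(apply(gram, 1, max))
  expect_lt(sd(nn) / mean(nn), 0.5)
  # balance: mean direction close to zero
  expect_lt(sqrt(sum(colMeans(d)^2)), 0.05)
  expect_error(generate_spoke_directions(0), "n >= 1")
})

test_that("interleaving partitions spokes into uniform subsets", {
  # protocol numbers: 120188 spokes at f = 20 -> 6009 per interleave
  il <- interleave_order(120188, 20)
  expect_equal(sum(il$interleave == 1, na.rm = TRUE), 6009)
  expect_equal(sum(is.na(il$interleave)), 120188 - 20 * 6009)
  expect_true(all(table(il$interleave) == 6009))
  # f = 1: identity grouping over the full set
  il1 <- interleave_order(10, 1)
  expect_equal(sort(il1$order), 1:10)
  expect_true(all(il1$interleave == 1))
  # union of interleaves = full spoke set (no loss, no duplication)
  il5 <- interleave_order(100, 5)
  expect_equal(sort(il5$order), 1:100)
  got <- sort(unlist(lapply(1:5, function(f) which(il5$interleave == f))))
  expect_equal(got, 1:100)
  # each interleave's nearest-neighbor angle statistics within 2x of a
  # fresh uniform set of the same size (pairwise-angle oracle)
  d <- generate_spoke_directions(100)
  ref <- generate_spoke_directions(20)
  nn_stat <- function(dd) {
    gram <- pmin(pmax(dd %*% t(dd), -1), 1)
    diag(gram) <- -1
    mean(acos(apply(gram, 1, max)))
  }
  ref_nn <- nn_stat(ref)
  for (f in 1:5) {
    sub <- d[il5$interleave == f, ]
    expect_lt(nn_stat(sub), 2 * ref_nn)
    expect_gt(nn_stat(sub), ref_nn / 2)
  }
  expect_error(interleave_order(10, 11), "must not exceed")
})

test_that("frame durations reproduce the protocol arithmetic", {
  # 256 lines x 32 averages x 12 ms = 98.304 s; + 4.546 s overhead = 1:42.85
  g <- image_grid(256, 0.059)
  sch <- cartesian_schedule(g, tr = 0.012, averages = 32, overhead_s = 0)
  expect_equal(cartesian_frame_duration(sch), 98.304)
  sch2 <- cartesian_schedule(g, tr = 0.012, averages = 32,
                             overhead_s = 4.546)
  expect_equal(cartesian_frame_duration(sch2), 102.85)
  expect_equal(format_scan_time(cartesian_frame_duration(sch2)), "1:42.85")
  # 1 line x 1 average x TR = TR
  g1 <- image_grid(2, 1)
  expect_equal(cartesian_frame_duration(
    cartesian_schedule(g1, tr = 0.5, averages = 1)), 1)
  # radial: 120188 spokes x 4 ms = 480.752 s = 8:00.75;
  # 5 subframes -> 96.1504 s = 1:36.15
  g3 <- image_grid(32, 0.35, dim = 3)
  rs <- radial_schedule(g3, n_spokes = 120188, f = 20, tr = 0.004)
  expect_equal(radial_frame_duration(rs, 1), 480.752)
  expect_equal(format_scan_time(radial_frame_duration(rs, 1)), "8:00.75")
  expect_equal(radial_frame_duration(rs, 5), 96.1504)
  expect_equal(format_scan_time(radial_frame_duration(rs, 5)), "1:36.15")
  expect_error(radial_frame_duration(rs, 3), "must divide")
  # 100 spokes x 10 ms = 1 s
  rs2 <- radial_schedule(g3, n_spokes = 100, f = 10, tr = 0.01)
  expect_equal(radial_frame_duration(rs2, 1), 1)
})

test_that("acquisition is deterministic and motion-sensitivity is localized", {
  g <- image_grid(32, 0.4)
  p <- particles(2, 1)
  sch <- cartesian_schedule(g, tr = 0.1, averages = 1)
  # noiseless static: repeated acquisitions identical
  scn <- scene(p, omega_rpm = 0, noise_sigma = 0)
  k1 <- acquire(scn, sch, seed = 1)
  k2 <- acquire(scn, sch, seed = 2)
  expect_identical(k1$data, k2$data)
  # same seed, with noise: identical
  scn_n <- scene(p, omega_rpm = 0, noise_sigma = 5)
  expect_identical(acquire(scn_n, sch, seed = 7)$data,
                   acquire(scn_n, sch, seed = 7)$data)
  # static vs rotating with the same seed: only particle phases differ,
  # so the difference never exceeds the void term magnitude
  scn_r <- scene(p, omega_rpm = 0.5, noise_sigma = 0)
  kr <- acquire(scn_r, sch, seed = 1)
  dmax <- 2 * 100 * 0.35 * 2 * pi * scn_r$particles$void_sigma[1]^2
  expect_true(all(Mod(kr$data - k1$data) <= dmax + 1e-9))
  expect_gt(max(Mod(kr$data - k1$data)), 0)
  # timestamps strictly increasing in acquisition order
  expect_true(all(diff(sort(as.vector(k1$timestamps))) > 0))
})

test_that("static Cartesian acquisition reconstructs the snapshot oracle", {
  g <- image_grid(64, 0.2)
  scn <- scene(particles(c(2, -1.4), c(1, 2.2)), omega_rpm = 0,
               noise_sigma = 0)
  sch <- cartesian_schedule(g, tr = 0.05, averages = 1)
  img <- cartesian_recon(acquire(scn, sch, seed = 1))
  # oracle: direct DFT recon of a single analytic snapshot
  kx <- rep(((1:64) - 33) / 12.8, 64)
  ky <- rep(((1:64) - 33) / 12.8, each = 64)
  snap <- matrix(analytic_kspace(scn, 0, cbind(kx, ky)), 64, 64)
  ks0 <- acquire(scn, sch, seed = 1)
  ks0$data <- snap
  oracle <- cartesian_recon(ks0)
  expect_lt(nrmse_to(as.vector(img), as.vector(oracle)), 1e-10)
})

test_that("dual half-echo radial sampling stores two echoes with deeper voids at the longer TE", {
  g <- image_grid(32, 0.35, dim = 3)
  scn <- scene(particles(2, 1, z0 = 0.5), dim = 3, noise_sigma = 0)
  sch <- radial_schedule(g, n_spokes = 300, f = 5)
  ks <- acquire(scn, sch, seed = 1)
  expect_equal(dim(ks$data), c(sch$samples_per_spoke, 300, 2))
  # echo-2 void term is scaled by echo2_contrast_scale: DC values differ
  dc1 <- Re(ks$data[1, 1, 1])            # center-out starts at DC
  dc2 <- Re(ks$data[sch$samples_per_spoke, 1, 2])  # center-in ends at DC
  disk_dc <- Re(analytic_kspace(scene(particles(numeric(0), numeric(0)),
                                      dim = 3), 0, matrix(0, 1, 3)))
  expect_lt(dc2, dc1)   # deeper void at longer TE removes more signal
  expect_lt(dc1, disk_dc)
})
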