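# Shared helpers: cached fixtures and spot measurement at ground truth.

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 1, sequence = "bssfp",
                           n_particles = 12) {
  key <- paste(name, seed, sequence, n_particles, sep = "_")
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_fixture(name, seed = seed, sequence = sequence,
                                     n_particles = n_particles)
  .fx_cache[[key]]
}

# positions of all particles at time t as a spot tibble
truth_spots <- function(scn, t) {
  th <- 2 * pi * scn$omega_rpm * t / 60
  p <- scn$particles
  tb <- tibble::tibble(
    id = p$id,
    x = cos(th) * p$x0 - sin(th) * p$y0,
    y = sin(th) * p$x0 + cos(th) * p$y0)
  if (scn$dim == 3) tb$z <- p$z0
  tb
}

measure_fixture <- function(fx, img, t) {
  measure_spots(img, truth_spots(fx$scene, t),
                mask = object_mask(fx$scene, fx$schedule$grid))
}

nrmse_to <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))

disk_interior_mask <- function(n, dx, r_inner) {
  ax <- ((seq_len(n) - 1) - n / 2 + 0.5) * dx
  sqrt(outer(ax^2, ax^2, `+`)) < r_inner
}
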