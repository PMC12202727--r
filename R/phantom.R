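#' Build a particle table for a digital phantom
#'
#' Particles stand in for micron-sized iron particles (MPIOs) or iron-labeled
#' cells. Each produces a point-like hypointense signal void modeled as a
#' Gaussian intensity dip of peak fractional depth `void_amplitude` and width
#' `void_sigma` (mm). `contrast_scale` is a per-sequence multiplier that
#' models the stronger T2* dephasing of GRE relative to bSSFP without
#' simulating the sequence physics.
#'
#' @param x0,y0,z0 coordinates (mm) at t = 0 in the phantom frame; the
#'   rotation axis is the origin. `z0` is ignored for 2D scenes.
#' @param void_amplitude fraction of background signal removed at the void
#'   center, in (0, 1].
#' @param void_sigma Gaussian width of the void in mm.
#' @param contrast_scale per-sequence contrast multiplier.
#' @return a tibble with one row per particle.
#' @export
particles <- function(x0, y0, z0 = 0, void_amplitude = 0.35,
                      void_sigma = 0.17, contrast_scale = 1) {
  n <- length(x0)
  tb <- tibble::tibble(
    id = seq_len(n), x0 = x0, y0 = y0, z0 = rep_len(z0, n),
    void_amplitude = rep_len(void_amplitude, n),
    void_sigma = rep_len(void_sigma, n),
    contrast_scale = rep_len(contrast_scale, n)
  )
  stopifnot(all(tb$void_amplitude > 0), all(tb$void_amplitude <= 1),
            all(tb$void_sigma > 0))
  tb
}

#' Rotating cylinder phantom scene
#'
#' Analytic ground-truth description of a cylindrical agar phantom containing
#' sparse point-like signal voids, rotating rigidly about its axis at a
#' constant rate. The scene can be evaluated in image space
#' ([render_image()]) and in k-space ([analytic_kspace()]) at any time.
#'
#' @param particles particle tibble from [particles()]; may have zero rows.
#' @param omega_rpm rotation rate in revolutions per minute (>= 0). The
#'   tangential speed of a particle at radius r mm is `2*pi*omega_rpm*r`
#'   mm/min.
#' @param cylinder_radius phantom radius in mm. The default 5.064 mm places
#'   the fastest particles of a 4.4e-3 rpm rotation at 0.14 mm/min.
#' @param background_signal background agar signal (arbitrary units).
#' @param noise_sigma SD of the complex Gaussian k-space noise added per
#'   sample during acquisition (same units as the k-space signal).
#' @param dim 2 for a disk slice (ideal thin-slab selection), 3 for a finite
#'   cylinder.
#' @param cyl_length cylinder length in mm (3D scenes).
#' @param slab_mm slab thickness metadata for 2D scenes (ideal integration).
#' @return an object of class `vl_scene`.
#' @export
scene <- function(particles = voidlapse::particles(numeric(), numeric()),
                  omega_rpm = 0, cylinder_radius = 5.064,
                  background_signal = 100, noise_sigma = 0,
                  dim = 2, cyl_length = 8, slab_mm = 0.3) {
  stopifnot(omega_rpm >= 0, cylinder_radius > 0, background_signal >= 0,
            noise_sigma >= 0, dim %in% c(2, 3))
  if (nrow(particles) > 0) {
    r <- sqrt(particles$x0^2 + particles$y0^2)
    if (any(r >= cylinder_radius))
      stop("all particles must lie inside the cylinder radius")
    if (dim == 3 && any(abs(particles$z0) >= cyl_length / 2))
      stop("all particles must lie inside the cylinder length")
  }
  structure(
    list(particles = particles, omega_rpm = omega_rpm,
         cylinder_radius = cylinder_radius,
         background_signal = background_signal,
         noise_sigma = noise_sigma, dim = dim,
         cyl_length = cyl_length, slab_mm = slab_mm),
    class = "vl_scene"
  )
}

#' @export
print.vl_scene <- function(x, ...) {
  cat(sprintf(
    "<vl_scene> %dD cylinder r = %.3f mm, B = %g, omega = %g rpm, %d particle(s), noise sd %g\n",
    x$dim, x$cylinder_radius, x$background_signal, x$omega_rpm,
    nrow(x$particles), x$noise_sigma))
  invisible(x)
}

# Instantaneous lab-frame positions of all particles (matrix n x dim).
positions_at <- function(scn, t) {
  p <- scn$particles
  th <- 2 * pi * scn$omega_rpm * t / 60
  x <- cos(th) * p$x0 - sin(th) * p$y0
  y <- sin(th) * p$x0 + cos(th) * p$y0
  if (scn$dim == 2) cbind(x = x, y = y) else cbind(x = x, y = y, z = p$z0)
}

#' Lab-frame position of a particle at time t
#'
#' Rigid rotation of the t = 0 position about the cylinder axis by the angle
#' `2*pi*omega_rpm*t/60`; the distance to the axis is conserved.
#'
#' @param scn a [scene()].
#' @param particle_id particle id (may be a vector).
#' @param t time in seconds (scalar, >= 0).
#' @return a tibble with columns id, x, y (and z for 3D scenes) in mm.
#' @export
particle_position <- function(scn, particle_id, t) {
  stopifnot(inherits(scn, "vl_scene"), t >= 0)
  idx <- match(particle_id, scn$particles$id)
  if (anyNA(idx)) stop("unknown particle id: ",
                       paste(particle_id[is.na(idx)], collapse = ", "))
  pos <- positions_at(scn, t)[idx, , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(id = particle_id, t = t),
                   tibble::as_tibble(pos))
}

#' Tangential speed of particles, mm/min
#'
#' `speed = 2*pi*omega_rpm*r` with r the distance to the rotation axis.
#'
#' @param omega_rpm rotation rate in rpm.
#' @param radius_mm distance to the axis in mm.
#' @export
tangential_speed <- function(omega_rpm, radius_mm) {
  2 * pi * omega_rpm * radius_mm
}

#' Image grid specification
#'
#' Centered grid, voxel centers at half-integer offsets from the rotation
#' axis; k-space DC at grid center.
#'
#' @param n voxels per axis (even; scalar or one per axis).
#' @param dx voxel size in mm.
#' @param dim image dimension (2 or 3); defaults to `length(n)` if n is a
#'   vector.
#' @export
image_grid <- function(n = 64, dx = 0.2, dim = if (length(n) > 1) length(n) else 2) {
  n <- rep_len(as.integer(n), dim)
  stopifnot(all(n > 0), all(n %% 2 == 0), dx > 0)
  structure(list(n = n, dx = dx, dim = dim, fov = n * dx), class = "vl_grid")
}

#' Render the analytic phantom on an image grid
#'
#' The object is `background * indicator(cylinder) * (1 - sum_i a_i * s_i *
#' exp(-|x - x_i(t)|^2 / (2 sigma_i^2)))`, clipped at zero, so voids appear
#' as hypointense spots.
#'
#' @param scn a [scene()].
#' @param t time in seconds.
#' @param grid an [image_grid()].
#' @return a `vl_image`: numeric array with voxel size and time attributes.
#' @export
render_image <- function(scn, t, grid) {
  stopifnot(inherits(scn, "vl_scene"), inherits(grid, "vl_grid"),
            grid$dim == scn$dim)
  ax <- lapply(seq_len(grid$dim), function(i) x_axis(grid$n[i], grid$dx))
  if (grid$dim == 2) {
    r2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
    mask <- r2 <= scn$cylinder_radius^2
  } else {
    r2xy <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
    mask <- outer(r2xy <= scn$cylinder_radius^2,
                  abs(ax[[3]]) <= scn$cyl_length / 2, `&`)
  }
  dip <- array(0, grid$n)
  if (nrow(scn$particles) > 0) {
    pos <- positions_at(scn, t)
    p <- scn$particles
    for (i in seq_len(nrow(p))) {
      d2 <- outer((ax[[1]] - pos[i, 1])^2, (ax[[2]] - pos[i, 2])^2, `+`)
      if (grid$dim == 3)
        d2 <- outer(d2, (ax[[3]] - pos[i, 3])^2, `+`)
      dip <- dip + p$void_amplitude[i] * p$contrast_scale[i] *
        exp(-d2 / (2 * p$void_sigma[i]^2))
    }
  }
  img <- scn$background_signal * mask * pmax(1 - dip, 0)
  vl_image(img, dx = grid$dx, t = t)
}

#' Interior mask of the phantom object
#'
#' Logical array marking voxels safely inside the cylinder (eroded by
#' `erode_vox` voxels), used to restrict background/enclosing-area sampling
#' to the object when quantifying spots near the phantom edge.
#'
#' @param scn a [scene()].
#' @param grid an [image_grid()].
#' @param erode_vox erosion margin in voxels.
#' @export
object_mask <- function(scn, grid, erode_vox = 2) {
  stopifnot(inherits(scn, "vl_scene"), inherits(grid, "vl_grid"),
            grid$dim == scn$dim)
  ax <- lapply(seq_len(grid$dim), function(i) x_axis(grid$n[i], grid$dx))
  rmax <- scn$cylinder_radius - erode_vox * grid$dx
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  if (grid$dim == 2) return(r2 <= rmax^2)
  outer(r2 <= rmax^2,
        abs(ax[[3]]) <= scn$cyl_length / 2 - erode_vox * grid$dx, `&`)
}

vl_image <- function(arr, dx, t = NA_real_) {
  structure(arr, dx = dx, t = t, class = c("vl_image", class(arr)))
}

#' @export
print.vl_image <- function(x, ...) {
  cat(sprintf("<vl_image> %s voxels, dx = %g mm, range [%.3g, %.3g]\n",
              paste(dim(x), collapse = " x "), attr(x, "dx"),
              min(x), max(x)))
  invisible(x)
}

# jinc-type closed form: 2 J1(z)/z with the z -> 0 limit.
jinc2 <- function(z) {
  out <- rep(1, length(z))
  nz <- abs(z) > 1e-12
  out[nz] <- 2 * besselJ(z[nz], 1) / z[nz]
  out
}

sinc_n <- function(u) {
  out <- rep(1, length(u))
  nz <- abs(u) > 1e-12
  out[nz] <- sin(pi * u[nz]) / (pi * u[nz])
  out
}

# Disk / finite-cylinder Fourier term (time-invariant under rotation).
cylinder_kspace <- function(scn, k) {
  kr <- sqrt(k[, 1]^2 + k[, 2]^2)
  out <- scn$background_signal * pi * scn$cylinder_radius^2 *
    jinc2(2 * pi * kr * scn$cylinder_radius)
  if (scn$dim == 3)
    out <- out * scn$cyl_length * sinc_n(k[, 3] * scn$cyl_length)
  out
}

#' Closed-form k-space of the phantom at time t
#'
#' Exact continuous Fourier transform (convention
#' `S(k) = integral I(x) exp(-2 pi i k.x) dx`, k in cycles/mm) of the
#' rendered object: a jinc-type disk/cylinder term minus one shifted
#' Gaussian term per void with phase `exp(-2 pi i k . x_i(t))`. Linear in
#' the particles; truncation of the Gaussians by the cylinder edge and the
#' zero clip are neglected (voids are small, interior, and shallow).
#'
#' @param scn a [scene()].
#' @param t time in seconds.
#' @param k numeric matrix (n x dim) of k-space coordinates in cycles/mm.
#' @param amplitude_scale extra multiplier on void amplitudes (used for the
#'   echo-2 contrast of the dual-half-echo acquisition).
#' @return complex vector of length nrow(k).
#' @export
analytic_kspace <- function(scn, t, k, amplitude_scale = 1) {
  stopifnot(inherits(scn, "vl_scene"))
  k <- as.matrix(k)
  stopifnot(ncol(k) == scn$dim, all(is.finite(k)))
  out <- as.complex(cylinder_kspace(scn, k))
  if (nrow(scn$particles) > 0) {
    p <- scn$particles
    pref <- scn$background_signal * p$void_amplitude * p$contrast_scale *
      amplitude_scale * (2 * pi * p$void_sigma^2)^(scn$dim / 2)
    decay <- 2 * pi^2 * p$void_sigma^2
    out <- out - void_kspace_sum(k, positions_at(scn, t), pref, decay)
  }
  out
}
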