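#' 2D Cartesian bSSFP/GRE acquisition schedule
#'
#' Time-stamped phase-encoding schedule for a 2D Cartesian acquisition.
#' Defaults follow the 2D Cartesian bSSFP protocol (TE/TR 6/12 ms, 32
#' averages, 256 x 256); `preset = "gre"` switches to the established GRE
#' time-lapse protocol (TE/TR 8/645 ms, 4 averages). Averages are acquired
#' line-by-line (all averages of one phase line consecutively) so the
#' effective time window of one k-space line is `averages * TR`; set
#' `averaging = "frame"` for frame-wise averaging.
#'
#' @param grid an [image_grid()] (2D).
#' @param tr,te repetition/echo time in seconds.
#' @param averages number of averages.
#' @param line_order `"linear"` (bottom-up) or `"centric"`.
#' @param overhead_s extra per-frame time (dummy scans etc.), seconds.
#' @param averaging `"line"` or `"frame"`.
#' @param preset `"bssfp"` or `"gre"`: fills tr/te/averages when not given.
#' @return object of class `vl_cartesian_schedule`.
#' @export
cartesian_schedule <- function(grid, tr = NULL, te = NULL, averages = NULL,
                               line_order = c("linear", "centric"),
                               overhead_s = 0, averaging = c("line", "frame"),
                               preset = c("bssfp", "gre")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    bssfp = list(tr = 0.012, te = 0.006, averages = 32L),
    gre   = list(tr = 0.645, te = 0.008, averages = 4L))
  tr <- tr %||% defaults$tr
  te <- te %||% defaults$te
  averages <- as.integer(averages %||% defaults$averages)
  line_order <- match.arg(line_order)
  averaging <- match.arg(averaging)
  stopifnot(inherits(grid, "vl_grid"), grid$dim == 2, tr > 0, averages >= 1)
  n_phase <- grid$n[2]
  ord <- if (line_order == "linear") seq_len(n_phase) else
    order(abs(seq_len(n_phase) - (n_phase / 2 + 0.5)))
  structure(
    list(grid = grid, tr = tr, te = te, averages = averages,
         line_order = line_order, phase_order = ord,
         overhead_s = overhead_s, averaging = averaging, preset = preset,
         type = "cartesian"),
    class = "vl_cartesian_schedule")
}

#' Duration of one Cartesian frame in seconds
#'
#' `n_phase * averages * TR + overhead`.
#' @param schedule a [cartesian_schedule()].
#' @export
cartesian_frame_duration <- function(schedule) {
  stopifnot(inherits(schedule, "vl_cartesian_schedule"))
  schedule$grid$n[2] * schedule$averages * schedule$tr + schedule$overhead_s
}

#' Quasi-uniform spoke directions on the sphere or circle
#'
#' 3D directions follow a generalized spiral phyllotaxis: uniform steps in
#' z with golden-angle azimuth increments, giving deterministic quasi-uniform
#' coverage of the full sphere whose stride-f subsets are themselves
#' quasi-uniform. 2D directions are uniformly spaced over 360 degrees.
#'
#' @param n number of spokes (>= 1).
#' @param dim 2 or 3.
#' @return n x dim matrix of unit vectors, ordered along the spiral path.
#' @export
generate_spoke_directions <- function(n, dim = 3) {
  stopifnot(n >= 1, dim %in% c(2, 3))
  if (dim == 2) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(x = cos(th), y = sin(th)))
  }
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))      # golden angle
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Interleaved acquisition ordering
#'
#' Partitions `n` spokes (ordered along the phyllotaxis path) into `f`
#' interleaves of `floor(n/f)` spokes by stride assignment (spoke j to
#' interleave `j mod f`), so every interleave covers k-space quasi-uniformly.
#' The acquisition order plays interleave 1 fully, then interleave 2, etc.
#' Remainder spokes (`n - f*floor(n/f)`) are acquired last and carry
#' interleave id `NA`: they contribute to fully sampled reconstructions but
#' to no subframe.
#'
#' @param n number of spokes.
#' @param f interleave factor, 1 <= f <= n.
#' @return list with `order` (acquisition-order permutation of 1..n) and
#'   `interleave` (per-spoke interleave id, 1..f or NA).
#' @export
interleave_order <- function(n, f) {
  stopifnot(n >= 1, f >= 1)
  if (f > n) stop("interleave factor f must not exceed the number of spokes")
  j <- seq_len(n) - 1
  per <- n %/% f
  interleave <- ifelse(j < f * per, j %% f + 1, NA_integer_)
  ord <- order(interleave, j, na.last = TRUE)
  list(order = ord, interleave = as.integer(interleave))
}

#' Interleaved 3D (or 2D) radial dual-half-echo schedule
#'
#' Center-out/center-in dual-half-echo radial acquisition with interleaved
#' spoke ordering. Defaults mirror the 3D radial bSSFP protocol
#' (TE1/TE2/TR = 0.65/3.33/4 ms, f = 20); spoke count and matrix are set by
#' the caller (the full protocol uses 120,188 spokes on a 196^3 grid).
#' A fraction `ramp_fraction` of each spoke's samples is acquired during the
#' gradient ramp, where |k| grows quadratically with sample index.
#'
#' @param grid an [image_grid()].
#' @param n_spokes number of spokes.
#' @param samples_per_spoke samples per half-echo readout.
#' @param f interleave factor.
#' @param tr,te1,te2 timing in seconds.
#' @param ramp_fraction fraction of samples on the gradient ramp.
#' @param dual_echo simulate both half echoes.
#' @param echo2_contrast_scale extra void-contrast multiplier for the second
#'   (longer-TE) echo; longer TE deepens iron-induced voids.
#' @return object of class `vl_radial_schedule`.
#' @export
radial_schedule <- function(grid, n_spokes, samples_per_spoke = NULL,
                            f = 20, tr = 0.004, te1 = 0.00065, te2 = 0.00333,
                            ramp_fraction = 0.2, dual_echo = TRUE,
                            echo2_contrast_scale = 1.3) {
  stopifnot(inherits(grid, "vl_grid"), n_spokes >= 1)
  samples_per_spoke <- samples_per_spoke %||% (max(grid$n) %/% 2 + 4)
  dirs <- generate_spoke_directions(n_spokes, grid$dim)
  il <- interleave_order(n_spokes, f)
  m <- samples_per_spoke
  n_ramp <- max(1L, round(ramp_fraction * m))
  speed <- pmin((seq_len(m) - 0.5) / n_ramp, 1)   # gradient ramps linearly
  kmag <- cumsum(speed)
  kmag <- kmag / kmag[m] * (1 / (2 * grid$dx))    # normalize to Nyquist
  kmag <- c(0, kmag[-m])                          # first sample at DC
  structure(
    list(grid = grid, n_spokes = n_spokes, samples_per_spoke = m,
         f = f, tr = tr, te1 = te1, te2 = te2,
         ramp_fraction = ramp_fraction, dual_echo = dual_echo,
         echo2_contrast_scale = echo2_contrast_scale,
         directions = dirs, order = il$order, interleave = il$interleave,
         kmag = kmag, type = "radial"),
    class = "vl_radial_schedule")
}

#' Duration of one fully sampled radial frame split into subframes
#'
#' `n_spokes * TR / n_subframes` seconds. `n_subframes` must divide the
#' interleave factor so that subframes are unions of whole interleaves.
#'
#' @param schedule a [radial_schedule()].
#' @param n_subframes number of subframes (1 = fully sampled).
#' @export
radial_frame_duration <- function(schedule, n_subframes = 1) {
  stopifnot(inherits(schedule, "vl_radial_schedule"))
  if (schedule$f %% n_subframes != 0)
    stop("n_subframes must divide the interleave factor f = ", schedule$f)
  schedule$n_spokes * schedule$tr / n_subframes
}

#' Format seconds as the m:ss.xx time strings used in scan protocols
#' @param seconds duration in seconds.
#' @export
format_scan_time <- function(seconds) {
  m <- floor(seconds / 60)
  s <- seconds - 60 * m
  sprintf("%d:%05.2f", m, s)
}

#' Simulate acquisition of a scene
#'
#' Samples the closed-form k-space of the (possibly rotating) scene along
#' the schedule's trajectory. The object is frozen during each readout
#' (readouts last ms, motion is mm/min) but moves between readouts, which is
#' the mechanism producing temporal blurring of moving voids. Independent
#' complex Gaussian noise of SD `scene$noise_sigma` is added per sample (and
#' per average). The dual-half-echo radial schedule produces two sample sets
#' per spoke, the second echo with `echo2_contrast_scale` on void contrast.
#'
#' @param scn a [scene()].
#' @param schedule a [cartesian_schedule()] or [radial_schedule()].
#' @param seed RNG seed for the noise (deterministic given seed).
#' @param frame_start start time of this frame in seconds.
#' @return object of class `vl_kspace`.
#' @export
acquire <- function(scn, schedule, seed = 1, frame_start = 0) {
  stopifnot(inherits(scn, "vl_scene"))
  if (inherits(schedule, "vl_cartesian_schedule"))
    acquire_cartesian(scn, schedule, seed, frame_start)
  else if (inherits(schedule, "vl_radial_schedule"))
    acquire_radial(scn, schedule, seed, frame_start)
  else stop("unsupported schedule type")
}

acquire_cartesian <- function(scn, schedule, seed, frame_start) {
  stopifnot(scn$dim == 2)
  g <- schedule$grid
  kx <- k_axis(g$n[1], g$dx)
  ky <- k_axis(g$n[2], g$dx)
  old <- .Random.seed_store(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  data <- matrix(0 + 0i, g$n[1], g$n[2])
  tstamp <- matrix(NA_real_, g$n[2], schedule$averages)
  moving <- nrow(scn$particles) > 0 && scn$omega_rpm > 0
  disk_cache <- NULL
  m <- 0L
  for (jj in seq_len(g$n[2])) {
    line <- schedule$phase_order[jj]
    k <- cbind(kx, ky[line])
    acc <- complex(g$n[1])
    for (a in seq_len(schedule$averages)) {
      idx <- if (schedule$averaging == "line") m else
        (a - 1L) * g$n[2] + (jj - 1L)
      t <- frame_start + idx * schedule$tr
      tstamp[line, a] <- t
      s <- analytic_kspace(scn, t, k)
      if (scn$noise_sigma > 0)
        s <- s + complex(real = rnorm(length(s), 0, scn$noise_sigma),
                         imaginary = rnorm(length(s), 0, scn$noise_sigma))
      acc <- acc + s
      m <- m + 1L
    }
    data[, line] <- acc / schedule$averages
  }
  structure(
    list(type = "cartesian", data = data, schedule = schedule,
         timestamps = tstamp, noise_sigma = scn$noise_sigma, seed = seed,
         frame_start = frame_start,
         frame_duration = cartesian_frame_duration(schedule)),
    class = "vl_kspace")
}

# Minimal deterministic RNG scoping without extra dependencies.
.Random.seed_store <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

acquire_radial <- function(scn, schedule, seed, frame_start) {
  stopifnot(scn$dim == schedule$grid$dim)
  old <- .Random.seed_store(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  m <- schedule$samples_per_spoke
  ns <- schedule$n_spokes
  d <- schedule$grid$dim
  echoes <- if (schedule$dual_echo) 2L else 1L
  # acquisition position of each spoke
  acq_pos <- integer(ns)
  acq_pos[schedule$order] <- seq_len(ns) - 1L
  samples <- array(0 + 0i, c(m, ns, echoes))
  tstamp <- matrix(NA_real_, ns, echoes)
  p <- scn$particles
  pref <- decay <- NULL
  if (nrow(p) > 0) {
    pref <- scn$background_signal * p$void_amplitude * p$contrast_scale *
      (2 * pi * p$void_sigma^2)^(d / 2)
    decay <- 2 * pi^2 * p$void_sigma^2
  }
  for (sp in seq_len(ns)) {
    dir <- schedule$directions[sp, ]
    k1 <- outer(schedule$kmag, dir)              # center-out
    disk <- cylinder_kspace(scn, k1)             # same |k| set for echo 2
    t_sp <- frame_start + acq_pos[sp] * schedule$tr
    for (e in seq_len(echoes)) {
      te <- if (e == 1) schedule$te1 else schedule$te2
      t <- t_sp + te
      tstamp[sp, e] <- t
      k <- if (e == 1) k1 else k1[m:1, , drop = FALSE]  # center-in
      s <- as.complex(if (e == 1) disk else disk[m:1])
      if (nrow(p) > 0) {
        sc <- if (e == 1) 1 else schedule$echo2_contrast_scale
        s <- s - void_kspace_sum(k, positions_at(scn, t), pref * sc, decay)
      }
      if (scn$noise_sigma > 0)
        s <- s + complex(real = rnorm(m, 0, scn$noise_sigma),
                         imaginary = rnorm(m, 0, scn$noise_sigma))
      samples[, sp, e] <- s
    }
  }
  structure(
    list(type = "radial", data = samples, schedule = schedule,
         timestamps = tstamp, noise_sigma = scn$noise_sigma, seed = seed,
         frame_start = frame_start,
         frame_duration = radial_frame_duration(schedule, 1)),
    class = "vl_kspace")
}

#' @export
print.vl_kspace <- function(x, ...) {
  cat(sprintf("<vl_kspace> %s, %s samples, noise sd %g\n", x$type,
              paste(dim(x$data), collapse = " x "), x$noise_sigma))
  invisible(x)
}
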