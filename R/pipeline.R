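# Desk-scale study conditions. Acquisition matrices and spoke counts are
# reduced relative to the scanner protocols, but frame durations, rotation
# rates and the resulting temporal blurring are preserved by scaling TR so
# that n_readouts * TR keeps the protocol frame time. Void width and noise
# are calibrated so the static observables (SL ~ 0.24, void ~ 3 px,
# CNR ~ 5-6 in the radial FS frame) match the rotating-phantom experiment.
desk_defaults <- list(
  n2d = 64L, dx2d = 0.2,
  n3d = 32L, dx3d = 0.35,
  cart_bssfp = list(averages = 4L, tr = 0.384, te = 0.006, overhead = 4.546),
  cart_gre   = list(averages = 4L, tr = 1.935, te = 0.008, overhead = 0),
  radial     = list(n_spokes = 2000L, f = 20L, tr = 480.752 / 2000,
                    te1 = 0.00065, te2 = 0.00333),
  noise2d = 18, noise3d = 0.55,
  amp2d = 0.27, amp3d = 0.24, sigma_vox2d = 0.75, sigma_vox3d = 0.85,
  gre_amp_scale = 0.9, gre_sigma_scale = 1.15,
  r_max = 4.2
)

# Deterministic particle layout: n particles spread over radii and angles.
default_particles <- function(n = 12, dim = 2, dx = desk_defaults$dx2d,
                              amp = if (dim == 2) desk_defaults$amp2d else
                                desk_defaults$amp3d,
                              sigma = (if (dim == 2) desk_defaults$sigma_vox2d
                                       else desk_defaults$sigma_vox3d) * dx,
                              contrast_scale = 1,
                              r_max = desk_defaults$r_max, seed = 42) {
  old <- .Random.seed_store(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  r <- seq(0.8, r_max, length.out = n)
  th <- seq_len(n) * pi * (3 - sqrt(5))   # golden-angle spacing: no overlaps
  particles(x0 = r * cos(th), y0 = r * sin(th),
            z0 = if (dim == 3) runif(n, -1.5, 1.5) else 0,
            void_amplitude = amp, void_sigma = sigma,
            contrast_scale = contrast_scale)
}

#' Named deterministic phantom fixtures
#'
#' Builds the study-condition bundles: a static reference and rotating
#' phantoms at the slow (4.4e-3 rpm, edge speeds up to 0.14 mm/min) and fast
#' (4.7e-2 rpm, up to 1.5 mm/min) rotation rates, acquired with the 2D
#' Cartesian bSSFP schedule; `"radial_static"` / `"radial_rotating"` use the
#' interleaved 3D radial dual-half-echo schedule. Deterministic for a fixed
#' seed. When `dir` is given, the scene (YAML), k-space (RDS) and reference
#' reconstruction (TIFF/NIfTI) are written there.
#'
#' @param name one of `"static_ref"`, `"rotating_slow"`, `"rotating_fast"`,
#'   `"radial_static"`, `"radial_rotating"`.
#' @param seed RNG seed for the k-space noise.
#' @param dir optional output directory.
#' @param n_particles number of embedded particles.
#' @param sequence Cartesian sequence preset for the 2D fixtures:
#'   `"bssfp"` or `"gre"` (GRE voids get a slightly wider, shallower dip
#'   plus the much longer effective per-line window of its schedule).
#' @return list with `scene`, `schedule`, `kspace` (invisible when writing).
#' @export
make_fixture <- function(name, seed = 1, dir = NULL, n_particles = 12,
                         sequence = c("bssfp", "gre")) {
  sequence <- match.arg(sequence)
  dd <- desk_defaults
  radial <- grepl("^radial", name)
  omega <- switch(name,
    static_ref = 0, rotating_slow = 4.4e-3, rotating_fast = 4.7e-2,
    radial_static = 0, radial_rotating = 4.4e-3,
    stop("unknown fixture name: ", name))
  if (radial) {
    grid <- image_grid(dd$n3d, dd$dx3d, dim = 3)
    p <- default_particles(n_particles, dim = 3, dx = dd$dx3d)
    scn <- scene(p, omega_rpm = omega, noise_sigma = dd$noise3d, dim = 3)
    sch <- radial_schedule(grid, n_spokes = dd$radial$n_spokes,
                           f = dd$radial$f, tr = dd$radial$tr,
                           te1 = dd$radial$te1, te2 = dd$radial$te2)
  } else {
    grid <- image_grid(dd$n2d, dd$dx2d, dim = 2)
    cs <- if (sequence == "gre") dd$gre_amp_scale else 1
    sg <- if (sequence == "gre") dd$gre_sigma_scale else 1
    p <- default_particles(n_particles, dim = 2, dx = dd$dx2d,
                           sigma = dd$sigma_vox2d * dd$dx2d * sg,
                           contrast_scale = cs)
    scn <- scene(p, omega_rpm = omega, noise_sigma = dd$noise2d, dim = 2)
    sq <- if (sequence == "gre") dd$cart_gre else dd$cart_bssfp
    sch <- cartesian_schedule(grid, tr = sq$tr, te = sq$te,
                              averages = sq$averages,
                              overhead_s = sq$overhead, preset = sequence)
  }
  ks <- acquire(scn, sch, seed = seed)
  out <- list(scene = scn, schedule = sch, kspace = ks)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_scene_yaml(scn, file.path(dir, paste0(name, "_scene.yaml")))
    write_kspace(ks, file.path(dir, paste0(name, "_kspace.rds")))
    img <- if (radial) grid_recon(ks) else cartesian_recon(ks)
    ext <- if (radial) ".nii.gz" else ".tif"
    write_image(img, file.path(dir, paste0(name, "_recon", ext)))
    return(invisible(out))
  }
  out
}

#' Experiment configuration
#'
#' A fully deterministic description of one simulate-reconstruct-quantify
#' run. Identical config + seed gives identical outputs; every random draw
#' flows from the single seed.
#'
#' @param fixture fixture name understood by [make_fixture()].
#' @param sequence `"cartesian_bssfp"`, `"cartesian_gre"` or
#'   `"radial_bssfp"`.
#' @param recon_mode `"FS"`, `"US"` or `"CS"`.
#' @param n_subframes subframes per FS frame for US/CS.
#' @param lambda_percent CS regularization weight (percent).
#' @param n_particles particles embedded in the phantom.
#' @param seed master seed.
#' @export
experiment_config <- function(fixture = "static_ref",
                              sequence = c("cartesian_bssfp", "cartesian_gre",
                                           "radial_bssfp"),
                              recon_mode = c("FS", "US", "CS"),
                              n_subframes = 1, lambda_percent = 1,
                              n_particles = 12, seed = 1) {
  sequence <- match.arg(sequence)
  recon_mode <- match.arg(recon_mode)
  if (recon_mode == "FS") n_subframes <- 1
  structure(list(fixture = fixture, sequence = sequence,
                 recon_mode = recon_mode, n_subframes = n_subframes,
                 lambda_percent = lambda_percent,
                 n_particles = n_particles, seed = seed),
            class = "vl_config")
}

#' Run the simulate - reconstruct - quantify pipeline
#'
#' Builds the fixture, reconstructs it in the requested mode, measures every
#' particle's signal void in every frame (at its ground-truth position at
#' the frame midpoint), and returns the frame series, spot table and a
#' machine-readable report.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for images, CSV and JSON report.
#' @return list with `frames` (`vl_frames`), `spots` (tibble), `report`
#'   (list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "vl_config"))
  fixture_name <- config$fixture
  if (config$sequence == "radial_bssfp" && !grepl("^radial", fixture_name))
    fixture_name <- paste0("radial_",
                           if (fixture_name == "static_ref") "static" else "rotating")
  fx <- withCallingHandlers(
    make_fixture(fixture_name, seed = config$seed,
                 n_particles = config$n_particles,
                 sequence = if (config$sequence == "cartesian_gre") "gre"
                            else "bssfp"),
    error = function(e) stop("simulate stage failed: ", conditionMessage(e)))
  ks <- fx$kspace
  frames <- tryCatch({
    if (ks$type == "cartesian") {
      frame_series(list(cartesian_recon(ks)), dx = ks$schedule$grid$dx,
                   mode = "FS", acceleration = 1,
                   start = 0, duration = ks$frame_duration)
    } else if (config$recon_mode == "CS") {
      cs_recon(ks, config$n_subframes,
               cs_config(lambda_percent = config$lambda_percent))
    } else {
      us_recon(ks, config$n_subframes)
    }
  }, error = function(e) stop("recon stage failed: ", conditionMessage(e)))
  spots <- tryCatch({
    purrr::map_dfr(seq_along(frames$frames), function(i) {
      tmid <- frames$frame_times$start_s[i] +
        frames$frame_times$duration_s[i] / 2
      pos <- positions_at(fx$scene, tmid)
      tb <- tibble::as_tibble(pos)
      tb$id <- fx$scene$particles$id
      m <- measure_spots(frames$frames[[i]], tb, dx = frames$dx, frame = i,
                         mask = object_mask(fx$scene, fx$schedule$grid))
      r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
      m$v_mm_per_min <- tangential_speed(fx$scene$omega_rpm, r)
      m
    })
  }, error = function(e) stop("quantify stage failed: ", conditionMessage(e)))
  report <- list(
    config = unclass(config),
    fixture = fixture_name,
    recon_mode = frames$mode,
    n_frames = length(frames$frames),
    frame_duration_s = frames$frame_times$duration_s[1],
    frame_duration = format_scan_time(frames$frame_times$duration_s[1]),
    mean_sl = mean(spots$sl), mean_cnr = mean(spots$cnr),
    mean_void_px = mean(spots$void_px),
    n_visible = sum(spots$visible), n_spots = nrow(spots))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spot_table(spots, file.path(out_dir, "spots.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (length(dim(frames$frames[[1]])) == 3)
      write_frames_nifti(frames, file.path(out_dir, "frames.nii.gz"))
    else
      write_image(frames$frames[[1]], file.path(out_dir, "frame1.tif"))
  }
  list(frames = frames, spots = spots, report = report)
}
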