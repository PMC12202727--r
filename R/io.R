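#' Serialize a scene to YAML
#' @param scn a [scene()].
#' @param path output file.
#' @export
write_scene_yaml <- function(scn, path) {
  stopifnot(inherits(scn, "vl_scene"))
  obj <- unclass(scn)
  obj$particles <- lapply(seq_len(nrow(scn$particles)), function(i)
    as.list(scn$particles[i, ]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a scene from YAML
#' @param path YAML file written by [write_scene_yaml()].
#' @export
read_scene_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- dplyr::bind_rows(lapply(obj$particles, tibble::as_tibble))
  if (nrow(p) == 0) p <- particles(numeric(), numeric())
  scene(particles = p, omega_rpm = obj$omega_rpm,
        cylinder_radius = obj$cylinder_radius,
        background_signal = obj$background_signal,
        noise_sigma = obj$noise_sigma, dim = obj$dim,
        cyl_length = obj$cyl_length, slab_mm = obj$slab_mm)
}

#' Write an image or volume to disk
#'
#' 3D volumes go to NIfTI with the voxel size in the header; 2D images to
#' TIFF (32-bit float, intensities stored as-is after scaling to \[0, 1\]
#' when requested).
#'
#' @param image a `vl_image`.
#' @param path output path (`.nii`/`.nii.gz` or `.tif`).
#' @param normalize divide by the maximum before writing TIFF.
#' @export
write_image <- function(image, path, normalize = TRUE) {
  d <- length(dim(image))
  dx <- attr(image, "dx")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- unclass(image)
    attributes(arr) <- list(dim = dim(arr))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(dx, d)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    stopifnot(d == 2)
    m <- unclass(image)
    attributes(m) <- list(dim = dim(m))
    if (normalize && max(m) > 0) m <- m / max(m)
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write a 4D frame series to NIfTI
#' @param frames a `vl_frames` (3D volumes).
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_frames_nifti <- function(frames, path) {
  stopifnot(inherits(frames, "vl_frames"))
  dm <- dim(frames$frames[[1]])
  stopifnot(length(dm) == 3)
  arr <- array(NA_real_, c(dm, length(frames$frames)))
  for (i in seq_along(frames$frames)) arr[, , , i] <- frames$frames[[i]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(frames$dx, 3),
                           frames$frame_times$duration_s[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a spot table as CSV
#' @param spots spot tibble from [measure_spots()].
#' @param path CSV path.
#' @export
write_spot_table <- function(spots, path) {
  readr::write_csv(spots, path)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) readr::read_csv(path, show_col_types = FALSE)

#' Save / load a simulated k-space bundle
#'
#' Complex samples, trajectory metadata and timestamps are kept in a single
#' serialized container (runtime artifact).
#'
#' @param kspace a `vl_kspace`.
#' @param path output `.rds` path.
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "vl_kspace"))
  saveRDS(kspace, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) readRDS(path)
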