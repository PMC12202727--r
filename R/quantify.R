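#' Signal loss of a hypointense spot
#'
#' `SL = (mean(enclosing) - min(spot)) / mean(enclosing)`: the per-particle
#' contrast metric. 0 for an invisible spot, 1 for a fully black void.
#'
#' @param spot intensities of the hypointense spot region (its minimum is
#'   used), or a single minimum value.
#' @param enclosing intensities of the enclosing area (its mean is used),
#'   or a single mean value.
#' @export
signal_loss <- function(spot, enclosing) {
  m <- mean(enclosing)
  if (!is.finite(m) || m <= 0) stop("enclosing mean must be positive")
  (m - min(spot)) / m
}

#' Void size in pixels
#'
#' Threshold at the average of the void minimum and the local background
#' intensity, then count the connected pixels below threshold that contain
#' the minimum. Degenerate case (background <= minimum) returns 1.
#'
#' @param image a 2D or 3D array.
#' @param center voxel index (vector) of the void minimum.
#' @param background background intensity estimate.
#' @param max_radius search cap in voxels around the center.
#' @param mask optional logical object mask; the fill stays inside it.
#' @return integer pixel count.
#' @export
void_size <- function(image, center, background, max_radius = 8,
                      mask = NULL) {
  dm <- dim(image)
  d <- length(dm)
  stopifnot(length(center) == d)
  vmin <- image[matrix(center, 1)]
  if (background <= vmin) return(1L)
  thr <- (vmin + background) / 2
  # flood fill (face connectivity) from the minimum within the cap
  lo <- pmax(center - max_radius, 1)
  hi <- pmin(center + max_radius, dm)
  sub <- if (d == 2) image[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
    image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sd_ <- dim(sub)
  below <- sub < thr
  if (!is.null(mask)) {
    msub <- if (d == 2) mask[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    below <- below & msub
  }
  lab <- array(FALSE, sd_)
  start <- center - lo + 1
  queue <- list(start)
  lab[matrix(start, 1)] <- TRUE
  steps <- rbind(diag(d), -diag(d))
  while (length(queue) > 0) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (s in seq_len(nrow(steps))) {
      nb <- cur + steps[s, ]
      if (any(nb < 1) || any(nb > sd_)) next
      im <- matrix(nb, 1)
      if (below[im] && !lab[im]) {
        lab[im] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  sum(lab)
}

#' Rayleigh-corrected noise SD from a background ROI
#'
#' The SD of magnitude-image background noise underestimates the underlying
#' complex-noise SD; multiplying by `sqrt(2/(4 - pi)) ~ 1.5264` recovers it
#' (Rayleigh statistics).
#'
#' @param samples background magnitude samples from outside the object.
#' @export
rayleigh_noise_sd <- function(samples) {
  if (length(samples) == 0) stop("empty background ROI")
  sd(samples) * sqrt(2 / (4 - pi))
}

#' The Rayleigh magnitude-noise correction constant, sqrt(2/(4-pi))
#' @export
rayleigh_correction <- function() sqrt(2 / (4 - pi))

#' SNR report from signal ROIs and a noise ROI
#'
#' SNR = mean ROI intensity / Rayleigh-corrected noise SD, averaged over
#' ROIs; SNR per unit time = SNR / scan time.
#'
#' @param image image array.
#' @param signal_rois list of index matrices or logical masks selecting
#'   signal ROIs.
#' @param noise_roi index matrix or logical mask of a background ROI outside
#'   the object.
#' @param scan_time_min scan time per frame in minutes (optional).
#' @return one-row tibble: n_rois, noise_sd, snr, scan_time_min, snr_per_min.
#' @export
snr <- function(image, signal_rois, noise_roi, scan_time_min = NA_real_) {
  roi_vals <- function(roi) if (is.logical(roi)) image[roi] else image[roi]
  nv <- roi_vals(noise_roi)
  nsd <- rayleigh_noise_sd(nv)
  means <- vapply(signal_rois, function(r) mean(roi_vals(r)), numeric(1))
  if (any(!is.finite(means))) stop("empty signal ROI")
  s <- mean(means / nsd)
  tibble::tibble(n_rois = length(signal_rois), noise_sd = nsd, snr = s,
                 scan_time_min = scan_time_min,
                 snr_per_min = s / scan_time_min)
}

#' SNR per unit time from an SNR value and a scan time
#' @param snr measured SNR.
#' @param scan_time_min scan time in minutes.
#' @export
snr_per_unit_time <- function(snr, scan_time_min) {
  stopifnot(scan_time_min > 0)
  snr / scan_time_min
}

#' Contrast-to-noise ratio of a signal void
#'
#' `CNR = (mean(enclosing) - min(spot)) / sd(enclosing)`.
#'
#' @param spot intensities (or minimum) of the hypointense spot.
#' @param enclosing intensities of the enclosing area.
#' @export
cnr <- function(spot, enclosing) {
  s <- sd(enclosing)
  if (!is.finite(s) || s <= 0) stop("enclosing SD must be positive")
  (mean(enclosing) - min(spot)) / s
}

#' Velocity-dependent change in signal loss
#'
#' `dSL = SL_stat - SL_rot`; for spots that are no longer visible in the
#' rotating acquisition, `SL_rot` is set to zero so `dSL = SL_stat`.
#'
#' @param sl_stat static signal loss (vectorized).
#' @param sl_rot rotating signal loss.
#' @param visible logical; spot still visible while rotating.
#' @export
delta_sl <- function(sl_stat, sl_rot, visible = TRUE) {
  stopifnot(all(sl_stat >= 0 & sl_stat <= 1))
  ifelse(rep_len(visible, length(sl_stat)), sl_stat - sl_rot, sl_stat)
}

#' Relative change in signal loss between FS and CS reconstructions
#'
#' `(SL_cs - SL_fs) / ((SL_cs + SL_fs)/2)`, in (-2, 2); positive when CS
#' deepens the void relative to the fully sampled reconstruction.
#'
#' @param sl_fs,sl_cs signal losses in the two reconstruction modes.
#' @export
relative_change_sl <- function(sl_fs, sl_cs) {
  if (any(sl_fs + sl_cs <= 0)) stop("SL_fs + SL_cs must be positive")
  (sl_cs - sl_fs) / ((sl_cs + sl_fs) / 2)
}

#' Percentage of particles that disappeared
#' @param n_not_visible count of spots no longer visible.
#' @param n_total total spots detected in the reference.
#' @export
percent_not_visible <- function(n_not_visible, n_total) {
  stopifnot(n_total > 0, n_not_visible >= 0, n_not_visible <= n_total)
  100 * n_not_visible / n_total
}

# mm coordinates -> voxel indices on the centered half-integer grid.
mm_to_voxel <- function(xy, n, dx) {
  out <- sapply(seq_along(n), function(i)
    pmin(pmax(round(xy[, i] / dx + n[i] / 2 + 0.5), 1), n[i]))
  matrix(out, ncol = length(n))
}

voxel_to_mm <- function(ij, n, dx) {
  out <- sapply(seq_along(n), function(i) (ij[, i] - n[i] / 2 - 0.5) * dx)
  matrix(out, ncol = length(n))
}

#' Measure hypointense spots in an image
#'
#' For each nominal spot coordinate: searches the void minimum in a
#' `5^d` voxel neighborhood (tolerating sub-voxel drift), estimates the
#' local background from a preliminary ring, thresholds at
#' `(min + background)/2` to obtain the connected void and its bounding
#' radius `r_v`, then samples the enclosing area as the annulus from
#' `r_v + 2` to `r_v + 5` voxels and reports signal loss, void size and CNR.
#' A spot is counted visible when its CNR exceeds `visible_cnr`.
#'
#' @param image a `vl_image` (or array with voxel size `dx`).
#' @param spots tibble with spot coordinates in mm: columns `x`, `y`
#'   (and `z` for 3D), optional `id`.
#' @param dx voxel size (taken from the image attribute when present).
#' @param search_halfwidth voxels searched around the nominal position.
#' @param annulus_offset,annulus_width enclosing-annulus geometry (voxels
#'   beyond the void bounding radius).
#' @param visible_cnr CNR threshold for the automated visibility call.
#' @param mask optional logical array marking object voxels (see
#'   [object_mask()]); background and enclosing-area sampling, the minimum
#'   search and the void fill are restricted to it, which keeps spots near
#'   the phantom edge measurable.
#' @param frame frame id stored in the output.
#' @return a spot table: one row per spot with columns id, frame, x, y, z,
#'   min, encl_mean, encl_sd, background, sl, void_px, cnr, visible.
#' @export
measure_spots <- function(image, spots, dx = attr(image, "dx"),
                          search_halfwidth = 2, annulus_offset = 2,
                          annulus_width = 3, visible_cnr = 2,
                          mask = NULL, frame = 1L) {
  dm <- dim(image)
  d <- length(dm)
  stopifnot(!is.null(dx), d %in% c(2, 3))
  coords <- as.matrix(spots[, intersect(c("x", "y", "z"), names(spots)),
                            drop = FALSE])
  stopifnot(ncol(coords) == d)
  ids <- spots$id %||% seq_len(nrow(spots))
  img <- unclass(image)
  rows <- lapply(seq_len(nrow(coords)), function(i) {
    ctr <- mm_to_voxel(coords[i, , drop = FALSE], dm, dx)[1, ]
    lo <- pmax(ctr - search_halfwidth, 1)
    hi <- pmin(ctr + search_halfwidth, dm)
    nb <- if (d == 2) img[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
      img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (!is.null(mask)) {
      mnb <- if (d == 2) mask[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
        mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      nb[!mnb] <- Inf
    }
    w <- arrayInd(which.min(nb), dim(nb))[1, ]
    ctr <- lo + w - 1
    vmin <- img[matrix(ctr, 1)]
    ring <- annulus_values(img, ctr, 4, 8, mask = mask)
    bg <- median(ring)
    vpx <- void_size(img, ctr, bg, mask = mask)
    rv <- void_bounding_radius(img, ctr, bg, mask = mask)
    encl <- annulus_values(img, ctr, rv + annulus_offset,
                           rv + annulus_offset + annulus_width, mask = mask)
    em <- mean(encl)
    es <- sd(encl)
    sl <- signal_loss(vmin, em)
    cn <- (em - vmin) / es
    pos <- voxel_to_mm(matrix(ctr, 1), dm, dx)
    tibble::tibble(id = ids[i], frame = frame,
                   x = pos[1], y = pos[2], z = if (d == 3) pos[3] else NA_real_,
                   min = vmin, encl_mean = em, encl_sd = es, background = bg,
                   sl = sl, void_px = vpx, cnr = cn, visible = cn >= visible_cnr)
  })
  dplyr::bind_rows(rows)
}

# Values in the annulus r0 < r <= r1 (voxels, Euclidean) around a center.
annulus_values <- function(img, center, r0, r1, mask = NULL) {
  dm <- dim(img)
  d <- length(dm)
  lo <- pmax(center - ceiling(r1), 1)
  hi <- pmin(center + ceiling(r1), dm)
  ax <- lapply(seq_len(d), function(i) (lo[i]:hi[i]) - center[i])
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  if (d == 3) r2 <- outer(r2, ax[[3]]^2, `+`)
  sub <- if (d == 2) img[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  keep <- r2 > r0^2 & r2 <= r1^2
  if (!is.null(mask)) {
    msub <- if (d == 2) mask[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    keep <- keep & msub
  }
  sub[keep]
}

# Bounding radius (voxels) of the connected void region, for annulus sizing.
void_bounding_radius <- function(img, center, background, max_radius = 8,
                                 mask = NULL) {
  dm <- dim(img)
  d <- length(dm)
  vmin <- img[matrix(center, 1)]
  if (background <= vmin) return(0)
  thr <- (vmin + background) / 2
  lo <- pmax(center - max_radius, 1)
  hi <- pmin(center + max_radius, dm)
  ax <- lapply(seq_len(d), function(i) (lo[i]:hi[i]) - center[i])
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  if (d == 3) r2 <- outer(r2, ax[[3]]^2, `+`)
  sub <- if (d == 2) img[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  below <- sub < thr
  if (!is.null(mask)) {
    msub <- if (d == 2) mask[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE] else
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    below <- below & msub
  }
  if (!any(below)) return(0)
  sqrt(max(r2[below]))
}
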