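#' Link spots across frames into trajectories
#'
#' Greedy globally-shortest-link nearest-neighbour matching per consecutive
#' frame pair (candidate links sorted by distance, ties broken by spot id):
#' each spot joins at most one trajectory, links longer than `max_disp` are
#' forbidden (trajectories terminate rather than swap), unmatched spots
#' start new trajectories. Optionally drops stationary features present in
#' every frame (small vessels mimic static cells in vivo).
#'
#' @param spots tibble with columns `frame`, `x`, `y` (and optionally `z`),
#'   coordinates in mm.
#' @param max_disp maximum link length in mm per frame pair.
#' @param exclude_stationary drop trajectories that appear in all frames and
#'   never move farther than `stationary_tol` from their start.
#' @param stationary_tol stationarity radius in mm.
#' @param min_frames minimum trajectory length kept (default 2 consecutive
#'   frames, singletons dropped; set to 1 to keep them).
#' @return the spot tibble with a `traj` column, filtered per the options.
#' @export
link_spots <- function(spots, max_disp, exclude_stationary = FALSE,
                       stationary_tol = max_disp / 10, min_frames = 2) {
  stopifnot(all(c("frame", "x", "y") %in% names(spots)), max_disp > 0)
  has_z <- "z" %in% names(spots) && !all(is.na(spots$z))
  cols <- c("x", "y", if (has_z) "z")
  spots <- dplyr::arrange(spots, .data$frame)
  spots$.row <- seq_len(nrow(spots))
  spots$traj <- NA_integer_
  frames <- sort(unique(spots$frame))
  next_traj <- 1L
  idx_f <- which(spots$frame == frames[1])
  spots$traj[idx_f] <- seq_along(idx_f)
  next_traj <- length(idx_f) + 1L
  for (fi in seq_along(frames)[-1]) {
    prev <- spots[spots$frame == frames[fi - 1] & !is.na(spots$traj), ]
    cur_idx <- which(spots$frame == frames[fi])
    if (nrow(prev) == 0 || length(cur_idx) == 0) {
      if (length(cur_idx) > 0) {
        spots$traj[cur_idx] <- next_traj + seq_along(cur_idx) - 1L
        next_traj <- next_traj + length(cur_idx)
      }
      next
    }
    cand <- expand.grid(p = seq_len(nrow(prev)), c = seq_along(cur_idx))
    dmat <- as.matrix(dist(rbind(as.matrix(prev[, cols]),
                                 as.matrix(spots[cur_idx, cols]))))
    dmat <- dmat[seq_len(nrow(prev)), nrow(prev) + seq_along(cur_idx),
                 drop = FALSE]
    cand$d <- dmat[cbind(cand$p, cand$c)]
    cand <- cand[cand$d <= max_disp, , drop = FALSE]
    cand <- cand[order(cand$d, prev$.row[cand$p], spots$.row[cur_idx][cand$c]), ,
                 drop = FALSE]
    used_p <- logical(nrow(prev)); used_c <- logical(length(cur_idx))
    for (r in seq_len(nrow(cand))) {
      p <- cand$p[r]; cc <- cand$c[r]
      if (used_p[p] || used_c[cc]) next
      used_p[p] <- TRUE; used_c[cc] <- TRUE
      spots$traj[cur_idx[cc]] <- prev$traj[p]
    }
    new_idx <- cur_idx[!used_c]
    if (length(new_idx) > 0) {
      spots$traj[new_idx] <- next_traj + seq_along(new_idx) - 1L
      next_traj <- next_traj + length(new_idx)
    }
  }
  out <- dplyr::group_by(spots, .data$traj)
  if (exclude_stationary) {
    n_frames <- length(frames)
    out <- dplyr::filter(out,
      !(dplyr::n() == n_frames &&
          max(sqrt((.data$x - .data$x[1])^2 + (.data$y - .data$y[1])^2 +
                     if (has_z) (.data$z - .data$z[1])^2 else 0)) <=
          stationary_tol))
  }
  out <- dplyr::filter(out, dplyr::n() >= min_frames)
  dplyr::select(dplyr::ungroup(out), -".row")
}

#' Per-trajectory velocities
#'
#' Mean velocity = total inter-frame path length / total elapsed time.
#'
#' @param trajectories output of [link_spots()].
#' @param frame_duration_min frame duration in minutes.
#' @return tibble: traj, n_frames, path_mm, displacement_mm, v_mm_per_min.
#' @export
traj_velocity <- function(trajectories, frame_duration_min) {
  stopifnot(frame_duration_min > 0)
  has_z <- "z" %in% names(trajectories) && !all(is.na(trajectories$z))
  trajectories |>
    dplyr::group_by(.data$traj) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      path_mm = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2 +
                           if (has_z) diff(.data$z)^2 else 0)),
      displacement_mm = sqrt((.data$x[dplyr::n()] - .data$x[1])^2 +
                               (.data$y[dplyr::n()] - .data$y[1])^2 +
                               if (has_z)
                                 (.data$z[dplyr::n()] - .data$z[1])^2 else 0),
      .groups = "drop") |>
    dplyr::mutate(v_mm_per_min = ifelse(.data$n_frames > 1,
      .data$path_mm / ((.data$n_frames - 1) * frame_duration_min), NA_real_))
}
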