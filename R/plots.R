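#' Plot an image with ggplot2
#'
#' Raster view of a reconstructed slice (2D image or one slice of a 3D
#' volume), axes in mm.
#'
#' @param object a `vl_image`.
#' @param slice z index for 3D volumes (default: middle slice).
#' @param ... unused.
#' @export
autoplot.vl_image <- function(object, slice = NULL, ...) {
  dm <- dim(object)
  dx <- attr(object, "dx")
  img <- if (length(dm) == 3) {
    slice <- slice %||% (dm[3] %/% 2)
    unclass(object)[, , slice]
  } else unclass(object)
  df <- expand.grid(x = x_axis(nrow(img), dx), y = x_axis(ncol(img), dx))
  df$intensity <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Relative change in signal loss versus velocity
#'
#' Scatter of the FS-to-CS relative change in signal loss against particle
#' velocity; points above zero mark particles whose visibility improves
#' with the accelerated CS reconstruction.
#'
#' @param spots_fs,spots_cs spot tables from [measure_spots()] on matching
#'   particles, with a `v_mm_per_min` column.
#' @export
plot_relative_change <- function(spots_fs, spots_cs) {
  stopifnot(all(spots_fs$id == spots_cs$id))
  df <- tibble::tibble(
    id = spots_fs$id, velocity = spots_fs$v_mm_per_min,
    rel_change = relative_change_sl(spots_fs$sl, spots_cs$sl),
    sl_stat = spots_fs$sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$velocity, y = .data$rel_change,
                                   colour = .data$sl_stat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "velocity (mm/min)",
                  y = "relative change SL (FS, CS)") +
    ggplot2::theme_minimal()
}

#' Facet view of a frame series
#' @param object a `vl_frames`.
#' @param slice z index for 3D volumes.
#' @param ... unused.
#' @export
autoplot.vl_frames <- function(object, slice = NULL, ...) {
  dfs <- purrr::map_dfr(seq_along(object$frames), function(i) {
    img <- object$frames[[i]]
    dm <- dim(img)
    m <- if (length(dm) == 3) {
      s <- slice %||% (dm[3] %/% 2)
      unclass(img)[, , s]
    } else unclass(img)
    df <- expand.grid(x = x_axis(nrow(m), object$dx),
                      y = x_axis(ncol(m), object$dx))
    df$intensity <- as.vector(m)
    df$frame <- i
    df
  })
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~frame) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s frames", object$mode)) +
    ggplot2::theme_minimal()
}
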