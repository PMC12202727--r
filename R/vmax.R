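#' Select the SL_stat bin entering a detection-limit fit
#'
#' Keeps records whose static signal loss lies in the closed interval
#' `[sl_center - halfwidth, sl_center + halfwidth]`.
#'
#' @param records tibble with at least `sl_stat`.
#' @param sl_center bin center.
#' @param halfwidth bin half-width (default 0.05).
#' @export
select_sl_bin <- function(records, sl_center, halfwidth = 0.05) {
  out <- dplyr::filter(records,
                       .data$sl_stat >= sl_center - halfwidth,
                       .data$sl_stat <= sl_center + halfwidth)
  if (nrow(out) == 0) stop("no records in the SL_stat bin around ", sl_center)
  out
}

# Ensure delta_sl and visible columns exist.
prepare_records <- function(records) {
  if (!"delta_sl" %in% names(records)) {
    stopifnot(all(c("sl_stat", "sl_rot", "visible") %in% names(records)))
    records$delta_sl <- delta_sl(records$sl_stat, records$sl_rot,
                                 records$visible)
  }
  stopifnot(all(c("velocity", "visible") %in% names(records)),
            all(records$velocity >= 0))
  records
}

#' Independent linear fits of dSL versus velocity per visibility group
#'
#' Ordinary least squares of the velocity-dependent change in signal loss,
#' fitted independently for visible and non-visible spots.
#'
#' @param records tibble with `velocity`, `delta_sl` (or `sl_stat`,
#'   `sl_rot`), `visible`.
#' @return list with `visible` and `non_visible` `lm` fits.
#' @export
fit_visibility_groups <- function(records) {
  records <- prepare_records(records)
  fit1 <- function(sub, label) {
    if (length(unique(sub$velocity)) < 2)
      stop("need >= 2 distinct velocities in the ", label, " group")
    lm(delta_sl ~ velocity, data = sub)
  }
  list(visible = fit1(dplyr::filter(records, .data$visible), "visible"),
       non_visible = fit1(dplyr::filter(records, !.data$visible),
                          "non-visible"))
}

# Intersection of two lines y = b + m v with first-order error propagation.
intersect_fits <- function(fit_vis, fit_nonvis, use_covariance = FALSE) {
  cv <- coef(fit_vis); cn <- coef(fit_nonvis)
  sv <- sqrt(diag(vcov(fit_vis))); sn <- sqrt(diag(vcov(fit_nonvis)))
  dm <- cv[["velocity"]] - cn[["velocity"]]
  if (abs(dm) < 1e-12)
    return(list(v_max = NA_real_, sigma = NA_real_, parallel = TRUE))
  v <- (cn[["(Intercept)"]] - cv[["(Intercept)"]]) / dm
  # dv/d(b_nv) = 1/dm, dv/d(b_v) = -1/dm, dv/d(m_v) = -v/dm, dv/d(m_nv) = v/dm
  grad_v <- c(-1 / dm, -v / dm)   # (b_v, m_v)
  grad_n <- c(1 / dm, v / dm)     # (b_nv, m_nv)
  var_v <- if (use_covariance) {
    drop(t(grad_v) %*% vcov(fit_vis) %*% grad_v +
           t(grad_n) %*% vcov(fit_nonvis) %*% grad_n)
  } else {
    sum(grad_v^2 * sv^2) + sum(grad_n^2 * sn^2)
  }
  list(v_max = v, sigma = sqrt(var_v), parallel = FALSE)
}

#' Estimate the velocity detection limit v_max
#'
#' Implements the dual-regression intersection procedure: records in the
#' `SL_stat` bin are split into visible and non-visible groups, dSL is
#' regressed on velocity independently in each group, and the intersection
#' of the two lines is the velocity detection limit. Its uncertainty comes
#' from first-order propagation of the standard errors of the four fit
#' parameters. By default the full within-fit covariance matrices are used,
#' which is identical to propagating independent standard errors after
#' centering velocity within each group (slope and intercept are then
#' uncorrelated); `use_covariance = FALSE` gives the naive version that
#' treats the raw intercept/slope SEs as independent, which overstates the
#' uncertainty when the group velocities are far from zero.
#'
#' @param records tibble with columns `velocity` (mm/min), `visible`, and
#'   either `delta_sl` or `sl_stat` + `sl_rot`. Non-visible spots follow the
#'   `SL_rot = 0` convention.
#' @param sl_center center of the `SL_stat` bin; `NULL` skips binning.
#' @param halfwidth bin half-width.
#' @param use_covariance propagate full fit covariances.
#' @return object of class `vmax_fit`.
#' @export
vmax_estimate <- function(records, sl_center = NULL, halfwidth = 0.05,
                          use_covariance = TRUE) {
  records <- prepare_records(records)
  if (!is.null(sl_center))
    records <- select_sl_bin(records, sl_center, halfwidth)
  fits <- fit_visibility_groups(records)
  inter <- intersect_fits(fits$visible, fits$non_visible, use_covariance)
  structure(
    list(v_max = inter$v_max, sigma = inter$sigma, parallel = inter$parallel,
         fits = fits, sl_center = sl_center, halfwidth = halfwidth,
         n_visible = sum(records$visible),
         n_non_visible = sum(!records$visible),
         records = records),
    class = "vmax_fit")
}

#' @export
print.vmax_fit <- function(x, ...) {
  if (x$parallel)
    cat("<vmax_fit> parallel fits: v_max undefined\n")
  else
    cat(sprintf("<vmax_fit> v_max = %.3f +/- %.3f mm/min (visible n = %d, non-visible n = %d)\n",
                x$v_max, x$sigma, x$n_visible, x$n_non_visible))
  invisible(x)
}

#' @rdname vmax_estimate
#' @param x a `vmax_fit`.
#' @param ... unused.
#' @export
tidy.vmax_fit <- function(x, ...) {
  one <- function(fit, group) {
    s <- summary(fit)$coefficients
    tibble::tibble(group = group,
                   term = c("intercept", "slope"),
                   estimate = s[, 1], std_error = s[, 2])
  }
  dplyr::bind_rows(one(x$fits$visible, "visible"),
                   one(x$fits$non_visible, "non_visible"))
}

#' @rdname vmax_estimate
#' @export
glance.vmax_fit <- function(x, ...) {
  tibble::tibble(v_max = x$v_max, sigma = x$sigma,
                 sl_center = x$sl_center %||% NA_real_,
                 n_visible = x$n_visible, n_non_visible = x$n_non_visible,
                 parallel = x$parallel)
}

#' @rdname vmax_estimate
#' @param object a `vmax_fit`.
#' @export
autoplot.vmax_fit <- function(object, ...) {
  rec <- object$records
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$velocity, y = .data$delta_sl,
                                    colour = .data$visible)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = coef(object$fits$visible)[1],
                         slope = coef(object$fits$visible)[2]) +
    ggplot2::geom_abline(intercept = coef(object$fits$non_visible)[1],
                         slope = coef(object$fits$non_visible)[2],
                         linetype = 2) +
    ggplot2::geom_vline(xintercept = object$v_max, colour = "red") +
    ggplot2::labs(x = "velocity (mm/min)", y = expression(Delta * "SL"),
                  title = sprintf("v_max = %.2f +/- %.2f mm/min",
                                  object$v_max, object$sigma)) +
    ggplot2::theme_minimal()
}

#' Detection-limit curve over static signal loss
#'
#' Repeats the v_max estimation for a series of `SL_stat` bin centers;
#' degenerate bins (empty, single-group, or parallel fits) are reported with
#' `NA` and a note instead of failing.
#'
#' @inheritParams vmax_estimate
#' @param sl_centers vector of bin centers.
#' @return tibble with one row per bin: sl_center, v_max, sigma, n_visible,
#'   n_non_visible, note.
#' @export
vmax_curve <- function(records, sl_centers, halfwidth = 0.05,
                       use_covariance = TRUE) {
  purrr::map_dfr(sl_centers, function(s) {
    res <- tryCatch(vmax_estimate(records, s, halfwidth, use_covariance),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("bin ", s, " skipped: ", conditionMessage(res), call. = FALSE)
      return(tibble::tibble(sl_center = s, v_max = NA_real_,
                            sigma = NA_real_, n_visible = NA_integer_,
                            n_non_visible = NA_integer_,
                            note = conditionMessage(res)))
    }
    tibble::tibble(sl_center = s, v_max = res$v_max, sigma = res$sigma,
                   n_visible = res$n_visible,
                   n_non_visible = res$n_non_visible,
                   note = if (res$parallel) "parallel fits" else NA_character_)
  })
}

#' Synthetic per-particle detection-limit records
#'
#' Generates (velocity, SL_stat, SL_rot, visible) records with a planted
#' velocity detection limit: visible spots lose contrast linearly with
#' velocity (`SL_rot = SL_stat - (SL_stat/v_max) * v` + noise) and spots
#' faster than `v_max` are non-visible (`SL_rot = 0`), so the visible-group
#' line and the flat non-visible line intersect at `v_max`. Mirrors the
#' rotating-phantom measurement at analysis scale.
#'
#' @param n number of records.
#' @param v_max_true planted detection limit, mm/min.
#' @param sl_center mean static signal loss.
#' @param sl_spread half-range of SL_stat scatter.
#' @param noise_sd SD of the measurement noise on dSL.
#' @param v_range velocities drawn uniformly over this range, mm/min.
#' @param seed RNG seed.
#' @return records tibble.
#' @export
simulate_vmax_records <- function(n = 60, v_max_true = 0.8,
                                  sl_center = 0.25, sl_spread = 0.03,
                                  noise_sd = 0.02,
                                  v_range = c(0, 2) * v_max_true,
                                  seed = 1) {
  old <- .Random.seed_store(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  v <- runif(n, v_range[1], v_range[2])
  sl_stat <- runif(n, sl_center - sl_spread, sl_center + sl_spread)
  slope <- sl_stat / v_max_true
  visible <- v < v_max_true
  sl_rot <- ifelse(visible,
                   pmax(sl_stat - slope * v + rnorm(n, 0, noise_sd), 0), 0)
  ds <- delta_sl(sl_stat, sl_rot, visible)
  ds[!visible] <- ds[!visible] + rnorm(sum(!visible), 0, noise_sd)
  tibble::tibble(id = seq_len(n), velocity = v, sl_stat = sl_stat,
                 sl_rot = sl_rot, visible = visible, delta_sl = ds)
}
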