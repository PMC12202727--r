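make_records <- function(v, ds, vis, sl = 0.25) {
  tibble::tibble(velocity = v, delta_sl = ds, visible = vis,
                 sl_stat = rep_len(sl, length(v)))
}

test_that("SL_stat bin selection uses the closed interval", {
  rec <- tibble::tibble(sl_stat = c(0.30, 0.31, 0.20, 0.19, 0.25),
                        velocity = 1:5, visible = TRUE, delta_sl = 0)
  sel <- select_sl_bin(rec, 0.25)
  expect_setequal(sel$velocity, c(1, 3, 5))   # 0.30 and 0.20 included
  expect_false(2 %in% sel$velocity)           # 0.31 excluded
  expect_error(select_sl_bin(rec, 0.9), "no records")
  # brute-force filter oracle on a random mixed set
  set.seed(9)
  rec2 <- tibble::tibble(sl_stat = runif(200, 0, 0.5), velocity = runif(200),
                         visible = TRUE, delta_sl = 0)
  brute <- sum(abs(rec2$sl_stat - 0.25) <= 0.05 |
                 abs(abs(rec2$sl_stat - 0.25) - 0.05) < 1e-12)
  expect_equal(nrow(select_sl_bin(rec2, 0.25)), brute)
})

test_that("group fits are ordinary least squares with textbook standard errors", {
  # exact line: dSL = 0.5 v
  v <- c(0.1, 0.3, 0.5, 0.7)
  fits <- suppressWarnings(fit_visibility_groups(make_records(
    c(v, 1.1, 1.5, 1.9), c(0.5 * v, 0.25, 0.25, 0.25),
    c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))))
  expect_equal(unname(coef(fits$visible)), c(0, 0.5), tolerance = 1e-12)
  expect_equal(unname(suppressWarnings(sqrt(diag(vcov(fits$visible))))),
               c(0, 0), tolerance = 1e-10)
  # noisy line against the closed-form OLS oracle
  set.seed(21)
  vv <- runif(40, 0, 2)
  yy <- 0.1 + 0.3 * vv + rnorm(40, 0, 0.05)
  f <- fit_visibility_groups(make_records(
    c(vv, 0.5, 1.5), c(yy, 0, 0), c(rep(TRUE, 40), FALSE, FALSE)))$visible
  sxx <- sum((vv - mean(vv))^2)
  b_hat <- sum((vv - mean(vv)) * (yy - mean(yy))) / sxx
  a_hat <- mean(yy) - b_hat * mean(vv)
  expect_equal(unname(coef(f)), c(a_hat, b_hat), tolerance = 1e-12)
  res <- yy - a_hat - b_hat * vv
  s2 <- sum(res^2) / 38
  expect_equal(unname(sqrt(diag(vcov(f)))[2]), sqrt(s2 / sxx),
               tolerance = 1e-12)
  # a single group present is an error
  expect_error(fit_visibility_groups(make_records(1:4 / 4, rep(0.1, 4),
                                                  rep(TRUE, 4))),
               "non-visible")
})

test_that("the fit intersection and its propagated error follow the algebra", {
  # visible dSL = 0.5 v; non-visible dSL = 0.2 + 0.1 v -> v_max = 0.5
  v1 <- c(0.05, 0.15, 0.25, 0.35)
  v2 <- c(0.6, 0.8, 1.0, 1.2)
  # exact lines: lm warns about the perfect fit, which is the point here
  fit <- suppressWarnings(vmax_estimate(make_records(
    c(v1, v2), c(0.5 * v1, 0.2 + 0.1 * v2),
    rep(c(TRUE, FALSE), each = 4))))
  expect_equal(fit$v_max, 0.5, tolerance = 1e-9)
  expect_equal(fit$sigma, 0, tolerance = 1e-7)  # all SEs zero
  expect_identical(glance(fit)$n_visible, 4L)
  expect_equal(nrow(suppressWarnings(tidy(fit))), 4)
  # parallel fits are flagged, not crashed
  par <- suppressWarnings(vmax_estimate(make_records(
    c(v1, v2), c(0.1 * v1, 0.3 + 0.1 * v2),
    rep(c(TRUE, FALSE), each = 4))))
  expect_true(par$parallel)
  expect_true(is.na(par$v_max))
})

test_that("the estimator is invariant to velocity unit rescaling", {
  rec <- simulate_vmax_records(n = 50, v_max_true = 0.8, seed = 3)
  f_mm <- vmax_estimate(rec, sl_center = 0.25)
  rec_um <- dplyr::mutate(rec, velocity = velocity * 1000)  # um/min
  f_um <- vmax_estimate(rec_um, sl_center = 0.25)
  expect_equal(f_um$v_max, 1000 * f_mm$v_max, tolerance = 1e-9)
  expect_equal(f_um$sigma, 1000 * f_mm$sigma, tolerance = 1e-9)
})

test_that("planted detection limits are recovered with calibrated uncertainty", {
  reps <- sapply(1:40, function(s) {
    rec <- simulate_vmax_records(n = 60, v_max_true = 0.8, seed = s)
    f <- vmax_estimate(rec, sl_center = 0.25)
    c(f$v_max, f$sigma)
  })
  # within +-2 sigma in at least 90% of replicates
  expect_gte(mean(abs(reps[1, ] - 0.8) <= 2 * reps[2, ]), 0.9)
  # propagated sigma within 2x of the Monte-Carlo SD
  expect_lt(mean(reps[2, ]) / sd(reps[1, ]), 2)
  expect_gt(mean(reps[2, ]) / sd(reps[1, ]), 0.5)
  # near-unbiased recovery
  expect_equal(mean(reps[1, ]), 0.8, tolerance = 0.05)
})

test_that("the detection-limit curve tracks a planted monotone trend", {
  # plant v_max increasing with SL_stat by stacking three record sets
  recs <- dplyr::bind_rows(lapply(1:3, function(i) {
    r <- simulate_vmax_records(n = 60, v_max_true = 0.3 + 0.25 * i,
                               sl_center = 0.1 + 0.12 * i, sl_spread = 0.03,
                               seed = 100 + i)
    r$id <- r$id + 1000 * i
    r
  }))
  curve <- vmax_curve(recs, c(0.22, 0.34, 0.46))
  expect_equal(nrow(curve), 3)
  expect_true(all(diff(curve$v_max) > 0))
  expect_equal(curve$v_max, 0.3 + 0.25 * (1:3), tolerance = 0.15)
  # single center reproduces the direct call
  single <- vmax_curve(recs, 0.34)
  direct <- vmax_estimate(recs, 0.34)
  expect_equal(single$v_max, direct$v_max)
  # an empty bin is flagged, not fatal
  expect_warning(bad <- vmax_curve(recs, c(0.34, 0.95)), "skipped")
  expect_true(is.na(bad$v_max[2]))
  expect_false(is.na(bad$v_max[1]))
})
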