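# voidlapse

Simulation, reconstruction and quantification toolkit for single-cell
**time-lapse MRI**: following individual iron-labeled cells — imaged as
hypointense signal voids — across repeated MRI frames, and measuring how
fast a cell can move before temporal blurring hides it.

`voidlapse` is aimed at MRI methods researchers who want to prototype and
stress-test the time-lapse analysis chain without scanner time. It
implements, end to end and at desk scale:

* an **analytic rotating phantom**: a cylinder of agar signal *B* with
  point-like Gaussian signal voids (depth *a*, width *σ*) that rotates
  rigidly at *ω* rpm, so every particle's speed `v = 2π ω r` is known
  exactly; the phantom is evaluable in closed form both in image space and
  in k-space at any time instant;
* **acquisition simulation** for 2D Cartesian bSSFP/GRE and interleaved 3D
  radial dual-half-echo bSSFP schedules, with per-readout timestamps (the
  object moves *between* readouts — the mechanism of temporal blurring) and
  complex Gaussian k-space noise;
* **reconstruction**: centered-FFT Cartesian recon, zero-filling contrast
  enhancement (4× finer grid + minimum intensity projection), ramp-filter
  density-compensated Kaiser–Bessel gridding (adjoint NUFFT), dual-echo
  weighted combination `(I1^(1+p) + I2^(1+p))^(1/(1+p))` with `p = −0.5`,
  retrospective fully-sampled / undersampled framing from the interleaved
  ordering, GRASP-style temporal-total-variation compressed sensing
  (`λ` as a percent of the adjoint recon maximum), and inverted maximum
  intensity projections;
* **quantification**: signal loss `SL = (mean(enclosing) − min)/mean(enclosing)`,
  void size by midpoint thresholding and connected-pixel counting, SNR and
  SNR per unit time, CNR with the Rayleigh magnitude-noise correction
  `√(2/(4−π)) ≈ 1.5264`, `ΔSL = SL_stat − SL_rot` (with `SL_rot := 0` for
  disappeared spots) and the FS↔CS relative change
  `(SL_CS − SL_FS)/((SL_CS + SL_FS)/2)`;
* the **velocity detection limit** `v_max`: ΔSL is regressed on velocity
  separately for visible and non-visible spots within an `SL_stat ± 0.05`
  bin, and the intersection of the two lines — with first-order error
  propagation of the fit parameters — is the speed at which voids stop
  being detectable;
* **nearest-neighbour spot tracking** with per-trajectory velocities.

Spot tables, detection-limit records and trajectories are tibbles; fitted
detection limits support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Compare temporal blurring between the fast bSSFP protocol (effective
per-line window 0.38 s) and the long-TR GRE protocol (2.6 s per line) on
the bundled rotating-phantom fixtures, at the fast rotation
(4.7 × 10⁻² rpm; edge speeds up to 1.5 mm/min):

```r
library(voidlapse)
library(dplyr)

blur <- purrr::map_dfr(c("bssfp", "gre"), function(sq) {
  static   <- make_fixture("static_ref",    seed = 1, sequence = sq)
  rotating <- make_fixture("rotating_fast", seed = 2, sequence = sq)
  mask <- object_mask(static$scene, static$schedule$grid)
  tmid <- rotating$kspace$frame_duration / 2
  m_stat <- cartesian_recon(static$kspace) |>
    measure_spots(particle_position(static$scene, 1:12, 0), mask = mask)
  m_rot <- cartesian_recon(rotating$kspace) |>
    measure_spots(particle_position(rotating$scene, 1:12, tmid), mask = mask)
  tibble(sequence = sq,
         sl_static = mean(m_stat$sl), sl_rotating = mean(m_rot$sl),
         dsl = mean(delta_sl(m_stat$sl, m_rot$sl, m_rot$visible)),
         void_px_rot = mean(m_rot$void_px))
})
blur
#> # A tibble: 2 × 5
#>   sequence sl_static sl_rotating    dsl void_px_rot
#>   <chr>        <dbl>       <dbl>  <dbl>       <dbl>
#> 1 bssfp        0.251       0.164 0.0868        4.92
#> 2 gre          0.239       0.106 0.132        3.58
```

Both sequences resolve the static particles with a mean signal loss of
~0.24–0.25, but once the phantom rotates, GRE voids lose far more contrast
(mean SL 0.11, mean ΔSL 0.13) than bSSFP voids (SL 0.16, ΔSL 0.09): the
short effective per-line window of bSSFP is what pushes the velocity
detection limit up.

The detection limit itself is estimated from per-particle
(velocity, ΔSL, visibility) records by the dual-regression intersection.
On synthetic records with a planted limit of 0.8 mm/min:

```r
records <- simulate_vmax_records(n = 60, v_max_true = 0.8, seed = 1)
fit <- vmax_estimate(records, sl_center = 0.25)
fit
#> <vmax_fit> v_max = 0.766 +/- 0.037 mm/min (visible n = 30, non-visible n = 30)
tidy(fit)
#> # A tibble: 4 × 4
#>   group       term      estimate std_error
#>   <chr>       <chr>        <dbl>     <dbl>
#> 1 visible     intercept -0.00498   0.00776
#> 2 visible     slope      0.320     0.0151
#> 3 non_visible intercept  0.233     0.0249
#> 4 non_visible slope      0.00972   0.0207
```

The visible group loses ~0.32 SL per mm/min of speed while the non-visible
group's ΔSL is flat at the static contrast; the lines intersect at
0.77 ± 0.04 mm/min, recovering the planted limit within one standard error.
`autoplot(fit)` draws the two regressions and the intersection;
`vmax_curve()` repeats the estimate over a series of `SL_stat` bins.

The full simulate → reconstruct → quantify chain is wrapped by
`run_pipeline(experiment_config(...))`, and a thin command-line wrapper
lives at `inst/cli/voidlapse.R`
(`Rscript inst/cli/voidlapse.R pipeline --fixture static_ref --seed 1 --out out/`).

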