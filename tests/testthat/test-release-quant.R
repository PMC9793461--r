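test_that("full-release concentration is dose over volume", {
  expect_identical(full_release_concentration(2, 500), 0.004)
  expect_identical(full_release_concentration(1, 500), 0.002)
  for (V in c(100, 250, 731.5)) {
    expect_equal(full_release_concentration(0.004 * V, V), 0.004)
  }
  expect_error(full_release_concentration(0, 500), "positive")
})

test_that("calibration requires a usable standard", {
  expect_error(probe_calibration("p1", default_standard(), -1), "positive")
  flat <- probe_calibration("p1", spectrum(200:300, rep(0, 101)), 0.004)
  s <- scaled_series(times = c(5, 10), fractions = c(0.2, 0.4),
                     base_spec = default_standard())
  expect_error(percent_released_single(s, flat), "not positive")
})

test_that("single-point readout is the sample/standard absorbance ratio", {
  cal <- default_calibration()
  times <- c(5, 10, 15)
  alpha <- c(0.25, 0.5, 1.0)
  s <- scaled_series(times = times, fractions = alpha,
                     base_spec = cal$standard_spectrum)
  prof <- percent_released_single(s, cal)
  expect_identical(prof$method, "single_point")
  expect_equal(prof$percent_released, 100 * alpha, tolerance = 1e-12)

  zero <- scaled_series(times = times, fractions = c(0, 0, 0),
                        base_spec = cal$standard_spectrum)
  expect_equal(percent_released_single(zero, cal)$percent_released,
               c(0, 0, 0))
})

test_that("smoothing derivative is polynomial-exact and validated", {
  const <- spectrum(200:300, rep(0.3, 101))
  expect_lt(max(abs(derivative_spectrum(const, 1)$absorbance)), 1e-12)
  expect_lt(max(abs(derivative_spectrum(const, 2)$absorbance)), 1e-12)

  lin <- spectrum(200:300, 0.01 * (200:300))
  expect_lt(max(abs(derivative_spectrum(lin, 1)$absorbance - 0.01)), 1e-12)

  expect_error(derivative_spectrum(lin, 1, window_points = 6), "odd")
  expect_error(derivative_spectrum(lin, 1, window_points = 3, poly_order = 2),
               "poly_order \\+ 2")
  expect_error(derivative_spectrum(spectrum(1:9 * 10, rep(1, 9)), 1,
                                   window_points = 11), "window larger")
  nonuni <- spectrum(c(200, 201, 203, 210, 230, 241, 255, 270, 290),
                     rep(0.2, 9))
  expect_error(derivative_spectrum(nonuni, 1), "uniform")
})

test_that("smoothing derivative tracks the analytic Gaussian derivative", {
  s <- default_standard()
  danal <- gaussian_band_deriv(200:300)
  # high polynomial order for fidelity against the analytic reference
  d <- derivative_spectrum(s, 1, window_points = 7, poly_order = 5)
  expect_lt(max(abs(d$absorbance - danal)), 1e-4 * max(abs(danal)))
})

test_that("analysis wavelength lands on the Gaussian inflection", {
  d <- derivative_spectrum(default_standard())
  expect_equal(select_analysis_wavelength(d, c(245, 265)), 252)
  # |derivative| rises monotonically toward the short-wavelength inflection
  expect_equal(select_analysis_wavelength(d, c(200, 230)), 230)
  flat <- derivative_spectrum(spectrum(200:300, rep(0.4, 101)))
  expect_error(select_analysis_wavelength(flat), "no usable extreme")
})

test_that("derivative readout cancels constant offsets, single-point does not", {
  cal <- default_calibration()
  grid <- cal$standard_spectrum$wavelength
  base <- 0.4 * cal$standard_spectrum$absorbance
  offsets <- c(0.02, 0.07, 0.11)
  A <- t(vapply(offsets, function(o) base + o, numeric(length(grid))))
  s <- spectral_series("v1", c(5, 10, 15), grid, A)

  dprof <- percent_released_derivative(s, cal)
  expect_identical(dprof$method, "first_derivative")
  expect_equal(dprof$percent_released, rep(40, 3), tolerance = 1e-9)

  sprof <- percent_released_single(s, cal)
  expect_true(all(abs(sprof$percent_released - 40) > 1))

  # sample identical to the standard -> exactly 100 %
  same <- scaled_series(times = c(5, 10), fractions = c(1, 1),
                        base_spec = cal$standard_spectrum)
  expect_equal(percent_released_derivative(same, cal)$percent_released,
               c(100, 100), tolerance = 1e-12)
})

test_that("a near-flat placebo admixture perturbs the derivative readout < 1 %", {
  cal <- default_calibration()
  grid <- cal$standard_spectrum$wavelength
  # tilt chosen so the placebo derivative is < 1 % of the standard's in
  # the analysis window (the premise of the error bound)
  plac <- pmax(0, 1 + 3e-4 * (grid - 241))
  dstd <- derivative_spectrum(cal$standard_spectrum)
  dplac <- derivative_spectrum(spectrum(grid, plac))
  w <- grid >= 245 & grid <= 260
  expect_lt(max(abs(dplac$absorbance[w])), 0.01 * max(abs(dstd$absorbance[w])))

  A <- rbind(0.4 * cal$standard_spectrum$absorbance + 0.3 * plac,
             0.4 * cal$standard_spectrum$absorbance + 0.6 * plac)
  s <- spectral_series("v1", c(5, 10), grid, A)
  dprof <- percent_released_derivative(s, cal)
  expect_true(all(abs(dprof$percent_released - 40) < 1))
})

test_that("second-derivative readout is available but tagged as such", {
  cal <- default_calibration()
  s <- scaled_series(times = c(5, 10), fractions = c(0.5, 1),
                     base_spec = cal$standard_spectrum)
  prof <- percent_released_derivative(s, cal, wavelength = 241, order = 2)
  expect_identical(prof$method, "second_derivative")
  expect_equal(prof$percent_released, c(50, 100), tolerance = 1e-9)
})

test_that("single-point and derivative methods agree without interference", {
  params <- simulation_params(seed = 314, placebo_rate = 0, noise_sd = 0)
  run <- synthesize_run(run_config(), params, n_vessels = 1)
  sp <- percent_released_single(run$series[[1]], run$standards[[1]])
  dp <- percent_released_derivative(run$series[[1]], run$standards[[1]])
  expect_lt(max(abs(sp$percent_released - dp$percent_released)), 0.5)
  # noiseless cumulative release is monotone under both readouts
  expect_true(all(diff(sp$percent_released) >= 0))
  expect_true(all(diff(dp$percent_released) >= 0))
})

test_that("vessel aggregation gives pointwise mean and sample sd", {
  p1 <- release_profile(c(5, 10), c(40, 80), method = "single_point")
  p2 <- release_profile(c(5, 10), c(60, 80), method = "single_point")
  agg <- aggregate_vessels(list(p1, p2))
  expect_equal(agg$percent_released, c(50, 80))
  expect_equal(agg$sd, c(sd(c(40, 60)), 0))
  expect_equal(agg$sd[1], 14.1421356, tolerance = 1e-6)

  same <- aggregate_vessels(list(p1, p1))
  expect_equal(same$percent_released, p1$percent_released)
  expect_equal(same$sd, c(0, 0))

  p3 <- release_profile(c(5, 15), c(60, 80), method = "single_point")
  expect_error(aggregate_vessels(list(p1, p3)), "time grids")
  p4 <- release_profile(c(5, 10), c(60, 80), method = "first_derivative")
  expect_error(aggregate_vessels(list(p1, p4)), "methods")
  expect_error(aggregate_vessels(list(p1)), "at least two")
})

test_that("aggregated mean of noisy replicates converges on the truth", {
  truth <- c(10, 30, 50, 70)
  set.seed(99)
  profs <- lapply(1:6, function(v) {
    release_profile(c(5, 10, 20, 40), truth + rnorm(4, sd = 2),
                    method = "single_point")
  })
  agg <- aggregate_vessels(profs)
  # CLT-style bound: mean within 3 * sd / sqrt(n) of truth at every point
  expect_true(all(abs(agg$percent_released - truth) <=
                    pmax(3 * agg$sd / sqrt(6), 1e-9)))
})

test_that("release profile CSV round-trips with and without sd", {
  prof <- release_profile(c(5, 10, 20), c(10.5, 30.25, 55.125),
                          sd = c(1, 2, 3), method = "first_derivative")
  path <- withr::local_tempfile(fileext = ".csv")
  write_release_profile(prof, path)
  back <- read_release_profile(path)
  expect_identical(back$times, prof$times)
  expect_identical(back$percent_released, prof$percent_released)
  expect_identical(back$sd, prof$sd)
  expect_identical(back$method, "first_derivative")

  nosd <- release_profile(c(5, 10, 20), c(1, 2, 3), method = "single_point")
  write_release_profile(nosd, path)
  expect_null(read_release_profile(path)$sd)
})

test_that("profiles are not clamped above 100 percent", {
  prof <- release_profile(c(5, 10), c(90, 108), method = "single_point")
  expect_equal(prof$percent_released[2], 108)
})
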