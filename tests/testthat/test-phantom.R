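# Synthetic cine generator: waveform contracts, determinism, ground truth.

test_that("pressure waveform hits diastole at the cycle ends and systole once", {
  p <- pressure_measurement(120, 80)
  expect_equal(pressure_waveform(0, p), 80)
  expect_equal(pressure_waveform(1, p), 80)
  expect_equal(pressure_waveform(0.35, p), 120)
  t <- seq(0, 1, by = 0.001)   # includes the systolic fraction 0.35
  w <- pressure_waveform(t, p)
  expect_equal(max(w), 120)
  expect_equal(min(w), 80)
  expect_equal(sum(abs(w - 120) < 1e-9), 1)        # systole exactly once
  # unimodal: increases to the peak, decreases after
  pk <- which.max(w)
  expect_true(all(diff(w[1:pk]) >= 0))
  expect_true(all(diff(w[pk:length(w)]) <= 0))
  # configurable systolic fraction
  expect_equal(pressure_waveform(0.5, p, systolic_fraction = 0.5), 120)
})

test_that("degenerate pressures are rejected", {
  expect_error(pressure_measurement(100, 100), class = "invalid_pressure")
  expect_error(pressure_measurement(80, 120), class = "invalid_pressure")
  expect_error(pressure_measurement(120, 0), class = "invalid_pressure")
  expect_error(pressure_waveform(1.5, pressure_measurement(120, 80)),
               class = "invalid_input")
})

test_that("phantom loops are deterministic given the seed", {
  spec <- phantom_spec(n_frames = 8L, seed = 42L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$loop$frames, b$loop$frames)
  c <- generate_phantom(phantom_spec(n_frames = 8L, seed = 43L))
  expect_false(identical(a$loop$frames[[1]], c$loop$frames[[1]]))
})

test_that("zero pulsation with zero noise gives bit-identical frames", {
  spec <- phantom_spec(peak_inner_radius_mm = 10, noise_sigma = 0,
                       n_frames = 8L, seed = 7L)
  ph <- generate_phantom(spec)
  for (k in 2:8) expect_identical(ph$loop$frames[[k]], ph$loop$frames[[1]])
})

test_that("ground-truth displacement closes the loop exactly", {
  ph <- small_phantom()
  pts <- cbind(runif(50, 10, 25), runif(50, 10, 25))
  expect_true(all(phantom_displacement(ph$spec, pts, 0) == 0))
  expect_true(all(phantom_displacement(ph$spec, pts, ph$spec$n_frames - 1) == 0))
  # inner wall lands exactly on a(t)
  ctr <- wallstrain:::phantom_center_mm(ph$spec)
  p_in <- matrix(c(ctr[1] + 10, ctr[2]), 1)
  a_t <- wallstrain:::phantom_a_of_frame(ph$spec)
  pk <- which.max(a_t)
  u <- phantom_displacement(ph$spec, p_in, pk - 1)
  expect_equal(10 + u[1, 1], a_t[pk], tolerance = 1e-12)
})

test_that("analytic mean principal strain matches the quadrature oracle", {
  spec <- phantom_spec(n_frames = 40L)
  a_t <- wallstrain:::phantom_a_of_frame(spec)
  pk <- which.max(a_t) - 1L
  expect_equal(analytic_mean_principal_strain(spec, 0), 0)
  expect_equal(analytic_mean_principal_strain(spec, spec$n_frames - 1), 0)
  for (fr in c(3L, 10L, pk)) {
    expect_equal(analytic_mean_principal_strain(spec, fr),
                 quadrature_mean_strain(10, 14, a_t[fr + 1]),
                 tolerance = 1e-6)
  }
  # peak frame dominates all others
  vals <- vapply(0:39, function(f) analytic_mean_principal_strain(spec, f),
                 numeric(1))
  expect_true(all(vals >= 0))
  expect_true(all(vals[pk + 1] >= vals))
  expect_error(analytic_mean_principal_strain(spec, 40), class = "invalid_input")
})

test_that("inner-wall circumferential Green strain has its closed-form value", {
  # lambda = a_peak / a0 = 1.05 -> E_theta = (lambda^2 - 1) / 2 = 0.05125
  spec <- phantom_spec(n_frames = 40L)
  ctr <- wallstrain:::phantom_center_mm(spec)
  a_t <- wallstrain:::phantom_a_of_frame(spec)
  pk <- which.max(a_t)
  u <- phantom_displacement(spec, matrix(c(ctr[1] + 10, ctr[2]), 1), pk - 1)
  lam <- (10 + u[1, 1]) / 10
  expect_equal(0.5 * (lam^2 - 1), 0.5 * ((a_t[pk] / 10)^2 - 1), tolerance = 1e-12)
  expect_equal(0.5 * ((10.5 / 10)^2 - 1), 0.05125)   # contract at a_peak
})

test_that("peak analytic mean strain increases strictly with a_peak", {
  peaks <- c(10.1, 10.25, 10.5, 10.8)
  vals <- vapply(peaks, function(apk) {
    spec <- phantom_spec(peak_inner_radius_mm = apk, n_frames = 16L)
    max(vapply(0:15, function(f) analytic_mean_principal_strain(spec, f),
               numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("a_peak_for_mean_strain inverts the closed-form mean strain", {
  for (tg in c(0.01, 0.02, 0.03, 0.05)) {
    apk <- a_peak_for_mean_strain(tg)
    expect_equal(quadrature_mean_strain(10, 14, apk), tg, tolerance = 1e-6)
  }
})

test_that("stiff sector with compliance 1 reproduces the homogeneous phantom", {
  s1 <- phantom_spec(n_frames = 8L, seed = 9L,
                     stiff_sector = list(start_deg = 0, end_deg = 90,
                                         compliance = 1))
  s0 <- phantom_spec(n_frames = 8L, seed = 9L)
  expect_identical(generate_phantom(s1)$loop$frames,
                   generate_phantom(s0)$loop$frames)
  expect_equal(analytic_mean_principal_strain(s1, 3),
               analytic_mean_principal_strain(s0, 3))
})

test_that("a stiff sector lowers wall strain inside the sector", {
  spec <- phantom_spec(n_frames = 8L, seed = 4L,
                       stiff_sector = list(start_deg = 20, end_deg = 110,
                                           compliance = 0.3))
  homog <- phantom_spec(n_frames = 8L, seed = 4L)
  pk <- 3L
  expect_lt(analytic_mean_principal_strain(spec, pk),
            analytic_mean_principal_strain(homog, pk))
  # sector-case quadrature self-consistency at two resolutions
  expect_equal(analytic_mean_principal_strain(spec, pk),
               analytic_mean_principal_strain(spec, pk, n_r = 900, n_theta = 1080),
               tolerance = 1e-5)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(inner_radius_mm = 15, outer_radius_mm = 14),
               class = "invalid_spec")
  expect_error(phantom_spec(peak_inner_radius_mm = 9), class = "invalid_spec")
  expect_error(phantom_spec(n_frames = 4), class = "invalid_spec")
  expect_error(phantom_spec(noise_sigma = -1), class = "invalid_spec")
  # annulus must fit in the image, including the systolic excursion
  big <- phantom_spec(inner_radius_mm = 14, outer_radius_mm = 18.2,
                      peak_inner_radius_mm = 14.5, n_frames = 8L)
  expect_error(generate_phantom(big), class = "geometry_error")
})
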