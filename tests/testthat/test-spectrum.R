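test_that("gaussian_profile matches the closed-form normal density", {
  g <- seq(-6, 6, 0.01)
  prof <- gaussian_profile(g, gaussian_component(0, 1, 1))
  # independent oracle: stats::dnorm
  expect_equal(prof, dnorm(g), tolerance = 1e-12)
  expect_equal(max(prof), 1 / sqrt(2 * pi), tolerance = 1e-4)

  # area parameterization: trapezoid integral over +/- 6 sigma recovers area
  for (case in list(c(291.5, 0.45, 5), c(0, 1, 1), c(10, 0.2, 3.7))) {
    grid <- seq(case[1] - 6 * case[2], case[1] + 6 * case[2], by = 0.01)
    sp <- pes_spectrum(grid, gaussian_profile(
      grid, gaussian_component(case[1], case[2], case[3])))
    expect_equal(spectrum_integral(sp), case[3], tolerance = 1e-3)
  }
  expect_error(gaussian_component(0, -1, 1), "sigma")
})

test_that("compose_vies adds excitation energies to the base ionization", {
  expect_equal(compose_vies(9.09), 9.09)
  expect_equal(compose_vies(7.95, c(0.92, 1.49)), c(7.95, 8.87, 9.44))
  expect_equal(compose_vies(5.0, 0.0), c(5.0, 5.0))
  expect_equal(compose_vies(5.0, c(2, 1)), c(5, 6, 7))  # sorted ascending
  expect_error(compose_vies(5.0, -0.1), ">= 0")
  expect_error(compose_vies(-1), "positive")
})

test_that("spectra simulated from VIE tables are sums of unit Gaussians", {
  # six coincident centers collapse to one Gaussian of six-fold area
  sp <- simulate_spectrum_from_vies(rep(291.5, 6), sigma = 0.45)
  ref <- gaussian_profile(sp$energy, gaussian_component(291.5, 0.45, 6))
  expect_equal(sp$intensity, ref, tolerance = 1e-12)

  # shoulder + main peak: global maximum at the five-fold site, shoulder
  # visible at the unique site
  sp2 <- simulate_spectrum_from_vies(c(292.9, rep(291.5, 5)), sigma = 0.45,
                                     grid = seq(288, 296, 0.001))
  expect_lt(abs(sp2$energy[which.max(sp2$intensity)] - 291.5), 0.05)
  at_shoulder <- sp2$intensity[which.min(abs(sp2$energy - 292.9))]
  expect_gt(at_shoulder, 0.15 * max(sp2$intensity))

  # one entry reduces to gaussian_profile
  sp3 <- simulate_spectrum_from_vies(9.09, sigma = 0.3)
  expect_equal(sp3$intensity,
               gaussian_profile(sp3$energy, gaussian_component(9.09, 0.3, 1)),
               tolerance = 1e-12)

  # total area equals the number of entries
  expect_equal(spectrum_integral(sp2), 6, tolerance = 6e-3)
  expect_error(simulate_spectrum_from_vies(numeric()), "empty")
})

test_that("area normalization fixes the windowed integral and keeps shape", {
  sp <- protonated_c1s()
  n1 <- area_normalize(sp, window = c(288, 296))
  expect_equal(spectrum_integral(n1, c(288, 296)), 1, tolerance = 1e-9)

  scaled <- sp
  scaled$intensity <- sp$intensity * 7
  n2 <- area_normalize(scaled, window = c(288, 296))
  expect_equal(n1$intensity, n2$intensity, tolerance = 1e-12)

  flat <- pes_spectrum(1:10, rep(0, 10))
  expect_error(area_normalize(flat), "not positive")
})

test_that("energy shifts translate the grid and compose with normalization", {
  sp <- protonated_c1s()
  expect_equal(shift_energy(sp, 0), sp)
  back <- shift_energy(shift_energy(sp, 0.3), -0.3)
  expect_equal(back$energy, sp$energy, tolerance = 1e-12)

  shifted <- shift_energy(sp, 0.2)
  expect_equal(shifted$energy[which.max(shifted$intensity)],
               sp$energy[which.max(sp$intensity)] + 0.2, tolerance = 1e-9)

  # shift and normalization commute when the window moves with the grid
  a <- area_normalize(shift_energy(sp, 0.37), c(288.37, 296.37))
  b <- shift_energy(area_normalize(sp, c(288, 296)), 0.37)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  expect_equal(a$energy, b$energy, tolerance = 1e-12)
})

test_that("reference-peak calibration recovers constructed offsets", {
  grid <- seq(8, 14, 0.01)
  water <- pes_spectrum(grid, gaussian_profile(
    grid, gaussian_component(11.33, 0.6, 1)), region = "valence")

  res <- calibrate_to_reference(shift_energy(water, 0.25), 11.33,
                                search_window = c(10, 13))
  expect_equal(res$detected_offset, 0.25, tolerance = 0.01)

  res0 <- calibrate_to_reference(water, 11.33, search_window = c(10, 13))
  expect_equal(res0$detected_offset, 0, tolerance = 0.01)
  expect_equal(res0$spectrum$energy, water$energy, tolerance = 0.01)

  # offset recovery across a range of offsets at SNR 100
  set.seed(421)
  errs <- vapply(seq(-0.3, 0.3, 0.1), function(off) {
    noisy <- perturb_spectrum(water, off, max(water$intensity) / 100,
                              seed = round(1000 * off) + 500)
    cal <- calibrate_to_reference(noisy, 11.33, search_window = c(10, 13))
    abs(cal$detected_offset - off)
  }, numeric(1))
  expect_lt(max(errs), 0.02)

  flat <- pes_spectrum(grid, rnorm(length(grid), 0, 1e-3))
  expect_error(calibrate_to_reference(flat, 11.33, c(10, 13)),
               "noise floor")
})

test_that("spectrum construction validates its grid and intensities", {
  expect_warning(s <- pes_spectrum(c(3, 2, 1), c(1, 2, 3)), "descending")
  expect_equal(s$energy, c(1, 2, 3))
  expect_equal(s$intensity, c(3, 2, 1))
  expect_error(pes_spectrum(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(pes_spectrum(c(1, 1, 2), c(1, 2, 3)), "monotonic")
  expect_error(pes_spectrum(c(1, 2, 3), c(1, NA, 3)), "finite")
  expect_error(pes_spectrum(1:3, 1:3, resolution_fwhm = -1), "resolution")
})
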