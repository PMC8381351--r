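test_that("endpoint conditions reproduce pure species spectra", {
  cfg <- synthetic_config(ph_values = c(2, 13), snr = Inf,
                          charging_offset_sd = 0)
  out <- make_c1s_series(cfg)
  # at pH far below the pKa the spectrum is the pure protonated envelope
  expected <- protonated_c1s(grid = cfg$grid)
  expect_lt(max(abs(out$series[[1]]$intensity - expected$intensity)), 1e-9)
})

test_that("generation is reproducible from the seed and records its draws", {
  cfg <- synthetic_config(seed = 42)
  a <- make_c1s_series(cfg)
  b <- make_c1s_series(cfg)
  for (i in seq_along(a$series)) {
    expect_identical(a$series[[i]]$intensity, b$series[[i]]$intensity)
    expect_identical(a$series[[i]]$energy, b$series[[i]]$energy)
    expect_identical(a$references[[i]]$intensity,
                     b$references[[i]]$intensity)
  }
  expect_identical(a$manifest, b$manifest)

  # the companion O 1s reference shares its acquisition's charging offset
  cal <- calibrate_to_reference(a$references[[1]], a$reference_center,
                                search_window = a$reference_center + c(-4, 4))
  expect_equal(cal$detected_offset, a$manifest$applied_offset_eV[1],
               tolerance = 0.01)

  # a different seed yields different noise
  c_ <- make_c1s_series(synthetic_config(seed = 43))
  expect_false(identical(a$series[[1]]$intensity, c_$series[[1]]$intensity))

  # manifest fractions follow the one-site equilibrium exactly
  expect_equal(a$manifest$true_fraction,
               hh_fraction(a$manifest$pH, cfg$true_pka), tolerance = 1e-12)
  expect_true(all(abs(a$manifest$applied_offset_eV) <= cfg$offset_bound))
})

test_that("perturbation applies offsets and seeded noise", {
  sp <- protonated_c1s()
  expect_equal(perturb_spectrum(sp, 0, 0), sp)

  # a single dominant reference line (the calibration use case)
  grid <- seq(530, 540, 0.01)
  o1s <- pes_spectrum(grid, gaussian_profile(
    grid, gaussian_component(535.05, 0.6, 1)), region = "O1s")
  cal <- calibrate_to_reference(perturb_spectrum(o1s, 0.3, 0), 535.05,
                                search_window = c(533, 537.5))
  expect_equal(cal$detected_offset, 0.3, tolerance = 0.02)

  n1 <- perturb_spectrum(sp, 0, 0.05, seed = 1)
  n1b <- perturb_spectrum(sp, 0, 0.05, seed = 1)
  n2 <- perturb_spectrum(sp, 0, 0.05, seed = 2)
  expect_identical(n1$intensity, n1b$intensity)
  expect_false(identical(n1$intensity, n2$intensity))
  expect_error(perturb_spectrum(sp, 0, -1), ">= 0")
})

test_that("valence spectra carry the pH-dependent solute fingerprint", {
  lo <- make_valence_spectrum(10)
  hi <- make_valence_spectrum(13)
  diffy <- hi$intensity - lo$intensity
  # the deprotonated-solute feature grows at 8.5 eV
  sol_region <- lo$energy > 7.5 & lo$energy < 8.9
  expect_true(all(diffy[sol_region] > 0))
  peak_at <- lo$energy[sol_region][which.max(diffy[sol_region])]
  expect_equal(peak_at, 8.5, tolerance = 0.15)

  # no solute and no hydroxide leaves the pure water background
  bg <- make_valence_spectrum(7, solute_scale = 0, hydroxide_scale = 0)
  bg2 <- make_valence_spectrum(3, solute_scale = 0, hydroxide_scale = 0)
  expect_equal(bg$intensity, bg2$intensity, tolerance = 1e-12)
})

test_that("the gas-phase water line is narrower than the liquid lines", {
  sp <- make_valence_spectrum(7, solute_scale = 0, hydroxide_scale = 0)
  fit_width <- function(window, center0) {
    m <- peak_model(list(gaussian_component(center0, 0.4, 0.3)))
    fit_peak_model(sp, m, fit_window = window)$components[[1]]$sigma
  }
  gas <- fit_width(c(12.25, 12.75), 12.5)
  liquid <- fit_width(c(16.2, 18.6), 17.4)
  expect_lt(gas, liquid)
})
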