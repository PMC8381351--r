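test_that("constrained two-Gaussian fit recovers the C 1s components", {
  sp <- protonated_c1s()
  model <- peak_model(
    list(gaussian_component(293.1, 0.5, 1),
         gaussian_component(291.3, 0.5, 5)),
    constraints = list(area_ratio(1, 2, 1 / 5)))
  fit <- fit_peak_model(sp, model, fit_window = c(288, 296))

  expect_true(fit$converged)
  centers <- vapply(fit$components, `[[`, numeric(1), "center")
  expect_equal(centers[1], 292.9, tolerance = 0.01)
  expect_equal(centers[2], 291.5, tolerance = 0.01)
  areas <- vapply(fit$components, `[[`, numeric(1), "area")
  # area-ratio constraint enforced by reparameterization, not penalty
  expect_equal(areas[1] / areas[2], 0.2, tolerance = 1e-15)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("area-ratio constraints hold exactly even on noisy data", {
  sp <- perturb_spectrum(deprotonated_c1s(),
                         noise_sd = max(deprotonated_c1s()$intensity) / 30,
                         seed = 11)
  model <- peak_model(
    list(gaussian_component(292.7, 0.5, 1),
         gaussian_component(291.4, 0.5, 5)),
    constraints = list(area_ratio(1, 2, 1 / 5)), share_sigma = TRUE)
  fit <- fit_peak_model(sp, model, fit_window = c(288, 296))
  areas <- vapply(fit$components, `[[`, numeric(1), "area")
  expect_equal(areas[1] / areas[2], 0.2, tolerance = 1e-15)
  sigmas <- vapply(fit$components, `[[`, numeric(1), "sigma")
  expect_identical(sigmas[1], sigmas[2])
})

test_that("fixed-center valence fit pins hydroxide and finds the solute", {
  # strong solute settings so the test probes the constraint machinery on
  # a well-conditioned problem
  sp <- make_valence_spectrum(13, solute_scale = 0.6, hydroxide_scale = 8,
                              grid = seq(6, 20, 0.01))
  model <- peak_model(
    list(gaussian_component(8.3, 0.5, 0.5),
         gaussian_component(9.2, 0.5, 0.8),
         gaussian_component(10.8, 0.7, 0.5)),  # liquid-water 1b1 edge
    constraints = list(fixed_center(2, 9.2)))
  fit <- fit_peak_model(sp, model, fit_window = c(7.2, 10.8))

  centers <- vapply(fit$components, `[[`, numeric(1), "center")
  expect_identical(centers[2], 9.2)
  expect_identical(fit$center_uncertainties[2], 0)
  expect_equal(centers[1], 8.5, tolerance = 0.15)
})

test_that("model validation rejects broken constraints", {
  comps <- list(gaussian_component(1, 1, 1), gaussian_component(2, 1, 1))
  expect_error(peak_model(comps, list(fixed_center(3, 1))), "outside")
  expect_error(peak_model(comps, list(area_ratio(1, 2, -1))), "positive")
  expect_error(
    peak_model(comps, list(area_ratio(1, 2, 2), area_ratio(2, 1, 2))),
    "circular")
})

test_that("two-basis unmixing recovers exact mixtures to machine precision", {
  a <- protonated_c1s()
  b <- deprotonated_c1s()

  expect_equal(fit_two_basis(a, a, b, align = FALSE)$ratio, 1.0)

  u <- fit_two_basis(mix_spectra(a, b, 0.37), a, b, align = FALSE)
  expect_equal(u$ratio, 0.37, tolerance = 1e-9)

  ramp <- seq(0, 1, 0.1)
  rec <- vapply(ramp, function(r) {
    fit_two_basis(mix_spectra(a, b, r), a, b, align = FALSE)$ratio
  }, numeric(1))
  expect_lt(max(abs(rec - ramp)), 1e-9)
  expect_true(all(diff(rec) > 0))

  expect_error(fit_two_basis(a, a, a, align = FALSE), "identical")
})

test_that("noisy-mixture unmixing is unbiased at paper-like noise", {
  a <- protonated_c1s()
  b <- deprotonated_c1s()
  truth <- mix_spectra(a, b, 0.5)
  noise_sd <- max(truth$intensity) / 50
  rec <- vapply(1:200, function(s) {
    fit_two_basis(perturb_spectrum(truth, 0, noise_sd, seed = s),
                  a, b, align = FALSE)$ratio
  }, numeric(1))
  expect_lt(abs(mean(rec) - 0.5), 0.02)
})

test_that("unmixing is invariant under global target shifts when aligned", {
  a <- protonated_c1s()
  b <- deprotonated_c1s()
  target <- mix_spectra(a, b, 0.6)
  r0 <- fit_two_basis(target, a, b, align = TRUE)$ratio
  for (delta in c(-0.3, -0.15, 0.15, 0.3)) {
    r <- fit_two_basis(shift_energy(target, delta), a, b,
                       align = TRUE)$ratio
    expect_equal(r, r0, tolerance = 0.01)
  }
})
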