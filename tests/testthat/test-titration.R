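test_that("the rearranged Henderson-Hasselbalch fraction obeys its identities", {
  expect_identical(hh_fraction(12.18, 12.18), 0.5)
  expect_equal(hh_fraction(10.18, 12.18), 1 / (1 + 1e-2), tolerance = 1e-12)

  # symmetry about the pKa and strict monotone decrease
  pka <- 11.7
  for (d in c(0.25, 1, 2.5)) {
    expect_equal(hh_fraction(pka + d, pka) + hh_fraction(pka - d, pka), 1,
                 tolerance = 1e-12)
  }
  ph <- seq(5, 20, 0.25)
  expect_true(all(diff(hh_fraction(ph, pka)) < 0))
  expect_equal(hh_fraction(1e6, pka), 0)
  expect_lt(abs(hh_fraction(-1e3, pka) - 1), 1e-12)
})

test_that("fit_pka recovers generating constants from clean fractions", {
  ph <- c(10.5, 11, 11.5, 12, 12.5)
  fit <- fit_pka(ph, hh_fraction(ph, 11.73))
  expect_equal(fit$pka, 11.73, tolerance = 1e-6)
  expect_equal(fit$fitted_curve(fit$pka), 0.5, tolerance = 1e-9)

  # a midpoint observation anchored by saturated endpoints
  fit2 <- fit_pka(c(6, 12, 18), c(1, 0.5, 0))
  expect_equal(fit2$pka, 12, tolerance = 0.01)

  # estimate is invariant under reordering of the points
  ord <- c(3, 1, 5, 2, 4)
  fit3 <- fit_pka(ph[ord], hh_fraction(ph, 11.73)[ord])
  expect_equal(fit3$pka, fit$pka, tolerance = 1e-9)
})

test_that("fit_pka is unbiased and stable under fraction noise", {
  ph <- seq(10, 13, 0.5)
  true_pka <- 11.5
  set.seed(77)
  est <- vapply(1:500, function(i) {
    r <- hh_fraction(ph, true_pka) + rnorm(length(ph), 0, 0.03)
    fit_pka(ph, pmin(1, pmax(0, r)))$pka
  }, numeric(1))
  expect_lt(abs(mean(est) - true_pka), 0.02)
  expect_lt(sd(est), 0.1)
})

test_that("fit_pka rejects degenerate inputs", {
  expect_error(fit_pka(12, 0.5), "insufficient")
  expect_error(fit_pka(c(10, 11, 12), c(1, 1, 1)), "unidentifiable")
  expect_error(fit_pka(c(10, 11, 12), c(0, 0, 0)), "unidentifiable")
  expect_error(fit_pka(c(10, 11), c(0.5, 3)), "fractions")
})

test_that("endpoint-impurity correction reproduces apparent ratios", {
  true_pka <- 12.18
  ph <- seq(10.5, 12.5, 0.5)
  f <- hh_fraction(ph, true_pka)
  f_lo <- hh_fraction(10, true_pka)
  f_hi <- hh_fraction(13, true_pka)
  apparent <- (f - f_hi) / (f_lo - f_hi)
  fit <- fit_pka(ph, apparent, basis_ph = c(10, 13))
  expect_equal(fit$pka, true_pka, tolerance = 1e-6)
  # fitting the same apparent ratios as plain fractions is biased
  fit_plain <- fit_pka(ph, apparent)
  expect_gt(abs(fit_plain$pka - true_pka), 0.01)
})

test_that("a deviating high-pH point raises the second-deprotonation flag", {
  ph <- seq(10, 13, 0.5)
  r <- hh_fraction(ph, 11.5)
  r[length(r)] <- r[length(r)] + 0.25
  fit <- fit_pka(ph, pmin(1, r))
  expect_true(fit$pka2_flag)
})

test_that("free-asymptote variant absorbs affine distortions of the curve", {
  ph <- seq(9, 14, 0.5)
  r <- 0.05 + 0.9 * hh_fraction(ph, 11.5)
  fit <- fit_pka(ph, r, free_asymptotes = TRUE)
  expect_equal(fit$pka, 11.5, tolerance = 1e-4)
  expect_equal(unname(fit$asymptotes["alpha"]), 0.05, tolerance = 1e-4)
  expect_equal(unname(fit$asymptotes["beta"]), 0.9, tolerance = 1e-4)
  expect_error(fit_pka(c(10, 11, 12), c(0.9, 0.5, 0.1),
                       free_asymptotes = TRUE), "four")
})

test_that("run_titration recovers the generating pKa from a clean series", {
  out <- make_c1s_series(synthetic_config(snr = Inf, charging_offset_sd = 0))
  res <- run_titration(out$series)
  expect_equal(res$pka, attr(out$manifest, "true_pka"), tolerance = 0.01)
  expect_false(res$extrapolation)
})

test_that("reference calibration removes charging offsets exactly", {
  out <- make_c1s_series(synthetic_config(snr = Inf,
                                          charging_offset_sd = 0.15,
                                          offset_bound = 0.3,
                                          o1s_snr = Inf, seed = 5))
  expect_gt(max(abs(out$manifest$applied_offset_eV)), 0.02)
  res <- run_titration(out$series, references = out$references,
                       reference_center = out$reference_center)
  expect_equal(res$pka, 12.18, tolerance = 0.01)
  expect_error(
    run_titration(out$series, references = out$references[1:2],
                  reference_center = out$reference_center),
    "parallel")
})

test_that("a series identical to the low-pH basis is unidentifiable", {
  base <- protonated_c1s(pH = 10)
  series <- lapply(c(10, 11, 12, 13), function(p) {
    s <- base
    s$meta$pH <- p
    s
  })
  expect_error(run_titration(series, align = FALSE), "identical|asymptote")
})
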