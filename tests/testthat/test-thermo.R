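test_that("the thermodynamic cycle combines free energies correctly", {
  expect_identical(dg_aqueous(10, -3, -5), 8)
  expect_identical(dg_aqueous(0, 0, 0), 0)
  # product side carries the solvated proton
  expect_equal(dg_aqueous(300, -20, -40 + proton_solvation_kcal), 14.1,
               tolerance = 1e-9)
  expect_identical(dg_aqueous(10, -3, -5, standard_state_correction = 1.9),
                   9.9)
})

test_that("pKa from free energy is linear with the right scale", {
  expect_identical(pka_from_dg(0), 0)
  rt_ln10 <- 8.31446 * 298.15 * log(10) / 4184
  expect_equal(rt_ln10, 1.3643, tolerance = 1e-4)
  expect_equal(pka_from_dg(rt_ln10), 1, tolerance = 1e-6)
  expect_equal(pka_from_dg(16.6), 12.2, tolerance = 0.05)
  expect_equal(pka_from_dg(2 * 7.3), 2 * pka_from_dg(7.3), tolerance = 1e-12)
  expect_error(pka_from_dg(1, temperature = 0), "positive")
})

test_that("Boltzmann populations of high-energy forms are tiny and bounded", {
  expect_identical(boltzmann_fraction(0)$fraction, 1)
  rt_ln2 <- 8.31446 * 298.15 * log(2) / 1000
  expect_equal(boltzmann_fraction(rt_ln2)$fraction, 0.5, tolerance = 1e-9)

  noncyclic <- boltzmann_fraction(26)
  expect_equal(noncyclic$fraction, 2.79e-5, tolerance = 0.01)
  expect_lt(noncyclic$percent, 0.003)

  de <- seq(0, 50, 5)
  fr <- vapply(de, function(e) boltzmann_fraction(e)$fraction, numeric(1))
  expect_true(all(fr > 0 & fr <= 1))
  expect_true(all(diff(fr) < 0))
})

test_that("energy unit conversions reproduce printed equivalences", {
  expect_equal(round(convert_energy(26, "kJ/mol", "eV"), 2), 0.27)
  expect_equal(convert_energy(-265.9, "kcal/mol", "kJ/mol"), -1112.5,
               tolerance = 0.1)
  expect_equal(convert_energy(1, "Hartree", "eV"), 27.2114, tolerance = 1e-3)

  # round trips and composition of conversions
  units <- c("kJ/mol", "kcal/mol", "eV", "Hartree")
  for (u in units) for (v in units) {
    x <- 17.3
    expect_equal(convert_energy(convert_energy(x, u, v), v, u), x,
                 tolerance = 1e-12)
    via <- convert_energy(convert_energy(x, u, "eV"), "eV", v)
    expect_equal(via, convert_energy(x, u, v), tolerance = 1e-12)
  }
  expect_error(convert_energy(1, "furlongs", "eV"), "unknown")
})

test_that("site ranking orders computed acidities and reports the gap", {
  pkas <- c(C1 = 11.3, C2 = 15.4, C3 = 15.5, C4 = 14.3, C6 = 17.3)
  rk <- rank_sites(pkas)
  expect_identical(rk$order, c("C1", "C4", "C2", "C3", "C6"))
  expect_equal(rk$first_gap, 3.0, tolerance = 1e-12)
  expect_length(rk$ties, 0)

  tied <- rank_sites(c(A = 1, B = 1, C = 2))
  expect_match(tied$ties, "A ~ B")
  expect_error(rank_sites(c(C1 = 11.3)), "two sites")
})

test_that("the cycle wrapper maps an energy table to per-site pKas", {
  tab <- data.frame(site = c("C1", "C4"),
                    dg_gas = c(330, 335),
                    dgsolv_reactants = c(-20, -20),
                    dgsolv_products = c(-45, -45) + proton_solvation_kcal)
  pk <- pka_thermo_cycle(tab)
  expect_named(pk, c("C1", "C4"))
  expect_equal(unname(pk["C4"] - pk["C1"]), 5 / 1.3643, tolerance = 1e-3)
  expect_error(pka_thermo_cycle(data.frame(site = "C1")), "columns")
})
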