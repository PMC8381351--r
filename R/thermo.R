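## Physical constants used throughout; CODATA values.
## R in J mol^-1 K^-1; energy-unit factors expressed in kJ/mol.
.gas_constant_J <- 8.31446
.kJ_per_unit <- c(
  `kJ/mol` = 1,
  `kcal/mol` = 4.184,
  `eV` = 96.485,
  `Hartree` = 2625.49964
)

#' Aqueous deprotonation free energy from a thermodynamic cycle
#'
#' Combines the gas-phase deprotonation free energy with the solvation free
#' energies of products and reactants:
#' \deqn{\Delta G_{aq} = \Delta G_{g} + \Delta G_{solv,prod} - \Delta G_{solv,react}}
#' The product-side solvation term includes the solvated proton; the
#' commonly used literature value for the proton solvation free energy is
#' -265.9 kcal/mol (see [proton_solvation_kcal]).
#'
#' @param dg_gas Gas-phase deprotonation free energy, kcal/mol.
#' @param dgsolv_reactants Solvation free energy of the neutral acid,
#'   kcal/mol.
#' @param dgsolv_products Total solvation free energy of the products
#'   (anion + proton), kcal/mol.
#' @param standard_state_correction Optional additive correction (kcal/mol)
#'   for gas-phase standard-state conventions (1 atm vs 1 M); default 0.
#' @return Aqueous free-energy change, kcal/mol.
#' @examples
#' dg_aqueous(300, -20, -40 + proton_solvation_kcal)  # 14.1
#' @export
dg_aqueous <- function(dg_gas, dgsolv_reactants, dgsolv_products,
                       standard_state_correction = 0) {
  dg_gas + dgsolv_products - dgsolv_reactants + standard_state_correction
}

#' Literature proton solvation free energy (kcal/mol)
#' @export
proton_solvation_kcal <- -265.9

#' pKa from an aqueous deprotonation free energy
#'
#' Standard relation `pKa = dG_aq / (R T ln 10)` with the free energy in
#' kcal/mol; linear in the free energy and zero at zero.
#'
#' @param dg_aq Aqueous deprotonation free energy, kcal/mol.
#' @param temperature Temperature in K (> 0), default 298.15.
#' @return pKa (unitless).
#' @examples
#' pka_from_dg(1.3643)   # ~ 1 at 298.15 K
#' @export
pka_from_dg <- function(dg_aq, temperature = 298.15) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be positive", call. = FALSE)
  }
  rt_kcal <- .gas_constant_J * temperature / 4184
  dg_aq / (rt_kcal * log(10))
}

#' Boltzmann population of a higher-energy form
#'
#' Fraction `exp(-dE / RT)` of a form lying `delta_e` above the reference
#' minimum, relative to the reference form (not normalized over a conformer
#' ensemble). Used e.g. to bound the abundance of noncyclic sugar forms.
#'
#' @param delta_e Energy above the reference form, kJ/mol (>= 0 for a
#'   population <= 1).
#' @param temperature Temperature in K (> 0), default 298.15.
#' @return A list with `fraction` and `percent`.
#' @examples
#' boltzmann_fraction(26)$percent   # ~ 0.0028 %
#' @export
boltzmann_fraction <- function(delta_e, temperature = 298.15) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be positive", call. = FALSE)
  }
  f <- exp(-delta_e * 1000 / (.gas_constant_J * temperature))
  list(fraction = f, percent = 100 * f)
}

#' Convert molecular energies between common units
#'
#' Supported units: kJ/mol, kcal/mol, eV (per particle, as molar
#' equivalent), Hartree. Conversions go through kJ/mol with CODATA factors;
#' round trips are exact to floating-point precision.
#'
#' @param value Numeric value(s).
#' @param from,to Unit names from `c("kJ/mol", "kcal/mol", "eV", "Hartree")`.
#' @return Converted value(s).
#' @examples
#' convert_energy(26, "kJ/mol", "eV")        # ~ 0.2695
#' convert_energy(-265.9, "kcal/mol", "kJ/mol")
#' @export
convert_energy <- function(value, from, to) {
  if (!from %in% names(.kJ_per_unit)) {
    stop("unknown energy unit: ", from, call. = FALSE)
  }
  if (!to %in% names(.kJ_per_unit)) {
    stop("unknown energy unit: ", to, call. = FALSE)
  }
  value * .kJ_per_unit[[from]] / .kJ_per_unit[[to]]
}

#' Rank deprotonation sites by acidity
#'
#' Orders per-site pKa values ascending (most acidic first) and reports the
#' gap between the most acidic site and the runner-up — the margin by which
#' one site dominates the first deprotonation equilibrium.
#'
#' @param pkas Named numeric vector (site -> pKa), at least two sites.
#' @param tie_tol Two pKas closer than this are flagged as tied.
#' @return A list with `order` (site labels, ascending pKa), `pkas` (sorted
#'   values), `first_gap` (pKa units) and `ties` (character vector of tied
#'   pairs, possibly empty).
#' @examples
#' rank_sites(c(C1 = 11.3, C2 = 15.4, C3 = 15.5, C4 = 14.3, C6 = 17.3))
#' @export
rank_sites <- function(pkas, tie_tol = 1e-9) {
  if (length(pkas) < 2L) {
    stop("at least two sites are required to rank", call. = FALSE)
  }
  if (is.null(names(pkas)) || any(!nzchar(names(pkas)))) {
    stop("`pkas` must be a named vector of site labels", call. = FALSE)
  }
  ord <- order(pkas)
  sorted <- pkas[ord]
  ties <- character()
  d <- diff(sorted)
  for (i in which(abs(d) <= tie_tol)) {
    ties <- c(ties, paste(names(sorted)[i], names(sorted)[i + 1L], sep = " ~ "))
  }
  list(order = names(sorted), pkas = sorted,
       first_gap = unname(sorted[2L] - sorted[1L]), ties = ties)
}

#' Thermodynamic-cycle pKa for one or more deprotonation sites
#'
#' Convenience wrapper chaining [dg_aqueous()] and [pka_from_dg()] over a
#' table of per-site free energies.
#'
#' @param energies A data.frame with columns `site`, `dg_gas`,
#'   `dgsolv_reactants`, `dgsolv_products` (all kcal/mol).
#' @param temperature Temperature in K.
#' @param standard_state_correction Additive correction, kcal/mol.
#' @return Named numeric vector of pKa values (one per site).
#' @export
pka_thermo_cycle <- function(energies, temperature = 298.15,
                             standard_state_correction = 0) {
  need <- c("site", "dg_gas", "dgsolv_reactants", "dgsolv_products")
  if (!all(need %in% names(energies))) {
    stop("`energies` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dg <- dg_aqueous(energies$dg_gas, energies$dgsolv_reactants,
                   energies$dgsolv_products,
                   standard_state_correction = standard_state_correction)
  stats::setNames(pka_from_dg(dg, temperature), energies$site)
}
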