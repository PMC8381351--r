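#' Configuration of the synthetic spectro-titration generator
#'
#' Defines the study conditions emulated by the generator: a 1 M weak-acid
#' solution probed by C 1s photoemission across an alkaline pH series. The
#' defaults mirror the measured system: protonated-species components at
#' 292.9 eV (C1 shoulder) and 291.5 eV (merged C2-C6) with a 1:5 area
#' ratio, deprotonated components at 292.5/291.5 eV, intrinsic Gaussian
#' broadening of sigma 0.45 eV combined in quadrature with a 0.28 eV FWHM
#' instrumental resolution, per-spectrum charging offsets of a few hundred
#' meV, and additive counting noise set by a signal-to-noise ratio at the
#' main-peak maximum.
#'
#' @param true_pka Ground-truth acid dissociation constant (default 12.18).
#' @param ph_values pH values of the series (default 10 to 13 in 0.5 steps).
#' @param grid Binding-energy grid in eV.
#' @param centers_prot,centers_deprot Component centers (eV) for the
#'   protonated and deprotonated species (shoulder first).
#' @param component_areas Component areas; `c(1, 5)` encodes the 1:5
#'   shoulder-to-main ratio of one unique site vs five merged sites.
#' @param intrinsic_sigma Intrinsic Gaussian sigma in eV.
#' @param instrument_fwhm Instrumental resolution (FWHM) in eV.
#' @param charging_offset_sd SD of the per-spectrum charging offset (eV),
#'   drawn from N(0, sd) truncated to `offset_bound`.
#' @param offset_bound Hard bound (eV) on charging offsets.
#' @param snr Signal-to-noise ratio at the main-peak maximum; `Inf` for
#'   noiseless spectra. Additive Gaussian noise with
#'   `sd = max(intensity)/snr`.
#' @param deprot2_fraction Optional fraction of a doubly-deprotonated
#'   contaminant mixed into the highest-pH spectrum (default 0), mimicking
#'   the onset of a second deprotonation equilibrium.
#' @param o1s_be,o1s_sigma,o1s_snr Companion solvent O 1s calibration line:
#'   liquid-water binding energy (config parameter, default 538.1 eV),
#'   Gaussian sigma (default 0.68 eV) and signal-to-noise ratio (default
#'   200 — the 55 M solvent line towers over the 1 M solute signal). Each
#'   acquisition's reference spectrum carries the same charging offset as
#'   its C 1s spectrum, as in a measurement where both come from the same
#'   charged liquid jet.
#' @param seed Integer seed; the full series is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(true_pka = 12.18,
                             ph_values = seq(10, 13, by = 0.5),
                             grid = seq(287, 297, by = 0.01),
                             centers_prot = c(292.9, 291.5),
                             centers_deprot = c(292.5, 291.5),
                             component_areas = c(1, 5),
                             intrinsic_sigma = 0.45,
                             instrument_fwhm = 0.28,
                             charging_offset_sd = 0.1,
                             offset_bound = 0.3,
                             snr = 50,
                             deprot2_fraction = 0,
                             o1s_be = 538.1,
                             o1s_sigma = 0.68,
                             o1s_snr = 200,
                             seed = 1L) {
  if (!length(ph_values)) stop("`ph_values` must be non-empty", call. = FALSE)
  if (intrinsic_sigma <= 0) stop("`intrinsic_sigma` must be > 0", call. = FALSE)
  if (charging_offset_sd < 0) stop("`charging_offset_sd` must be >= 0", call. = FALSE)
  if (snr <= 0) stop("`snr` must be positive (use Inf for noiseless)", call. = FALSE)
  structure(
    list(true_pka = true_pka, ph_values = sort(as.numeric(ph_values)),
         grid = grid, centers_prot = centers_prot,
         centers_deprot = centers_deprot, component_areas = component_areas,
         intrinsic_sigma = intrinsic_sigma, instrument_fwhm = instrument_fwhm,
         charging_offset_sd = charging_offset_sd, offset_bound = offset_bound,
         snr = snr, deprot2_fraction = deprot2_fraction,
         o1s_be = o1s_be, o1s_sigma = o1s_sigma, o1s_snr = o1s_snr,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# Noiseless pure-species basis spectrum on the config grid.
species_basis_spectrum <- function(config, species = c("protonated",
                                                       "deprotonated")) {
  species <- match.arg(species)
  centers <- if (species == "protonated") config$centers_prot else
    config$centers_deprot
  sig <- combine_sigma(config$intrinsic_sigma, config$instrument_fwhm)
  y <- rep(0, length(config$grid))
  for (k in seq_along(centers)) {
    y <- y + gaussian_profile(
      config$grid, gaussian_component(centers[k], sig,
                                      config$component_areas[k]))
  }
  pes_spectrum(config$grid, y, region = "C1s",
               resolution_fwhm = config$instrument_fwhm, label = species)
}

#' Generate a synthetic C 1s titration series with known ground truth
#'
#' For each pH the protonated fraction `f` follows
#' [hh_fraction()]`(pH, true_pka)`; the ideal spectrum is
#' `f * protonated_basis + (1 - f) * deprotonated_basis`, then a charging
#' offset is drawn and applied and Gaussian noise added ([perturb_spectrum()]).
#' Every random draw is recorded in the manifest; the series is
#' bit-reproducible from `config$seed`.
#'
#' Alongside each C 1s spectrum, a companion solvent O 1s reference
#' spectrum is generated with the *same* charging offset — emulating the
#' calibration measurement taken from each solution — so that downstream
#' analysis can cancel charging against an external reference line
#' instead of consuming C 1s information for self-alignment.
#'
#' @param config A [synthetic_config()].
#' @return A list with `series` (list of [pes_spectrum()], ascending pH),
#'   `references` (parallel list of O 1s calibration spectra),
#'   `reference_center` (the config's O 1s binding energy, eV) and
#'   `manifest` (data.frame with `pH`, `true_fraction`, `applied_offset_eV`,
#'   `noise_sd`, `seed`; attribute `true_pka`).
#' @examples
#' out <- make_c1s_series(synthetic_config(snr = Inf, charging_offset_sd = 0))
#' run_titration(out$series)
#' @export
make_c1s_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  prot <- species_basis_spectrum(config, "protonated")
  deprot <- species_basis_spectrum(config, "deprotonated")

  n <- length(config$ph_values)
  offsets <- numeric(n)
  seeds <- (abs(config$seed) %% 1000000L) * 1000L + seq_len(n)
  set.seed(config$seed)
  for (i in seq_len(n)) {
    offsets[i] <- draw_bounded_normal(config$charging_offset_sd,
                                      config$offset_bound)
  }

  ref_grid <- seq(config$o1s_be - 5, config$o1s_be + 5, by = 0.01)
  ref_ideal <- gaussian_profile(
    ref_grid, gaussian_component(config$o1s_be, config$o1s_sigma, 1))

  series <- vector("list", n)
  references <- vector("list", n)
  fr <- hh_fraction(config$ph_values, config$true_pka)
  noise_sds <- numeric(n)
  for (i in seq_len(n)) {
    f <- fr[i]
    y <- f * prot$intensity + (1 - f) * deprot$intensity
    if (config$deprot2_fraction > 0 && i == n) {
      # crude second-deprotonation contaminant: shift the deprotonated
      # envelope a further 0.4 eV down in BE
      contam <- interpolate_spectrum(shift_energy(deprot, -0.4), config$grid)
      y <- (1 - config$deprot2_fraction) * y +
        config$deprot2_fraction * contam$intensity
    }
    ideal <- pes_spectrum(config$grid, y, pH = config$ph_values[i],
                          region = "C1s",
                          resolution_fwhm = config$instrument_fwhm,
                          label = sprintf("synthetic pH %.1f",
                                          config$ph_values[i]))
    noise_sds[i] <- if (is.finite(config$snr)) max(y) / config$snr else 0
    series[[i]] <- perturb_spectrum(ideal, offset = offsets[i],
                                    noise_sd = noise_sds[i], seed = seeds[i])

    ref <- pes_spectrum(ref_grid, ref_ideal, pH = config$ph_values[i],
                        region = "O1s",
                        resolution_fwhm = config$instrument_fwhm,
                        label = sprintf("O 1s reference pH %.1f",
                                        config$ph_values[i]))
    ref_noise <- if (is.finite(config$o1s_snr)) {
      max(ref_ideal) / config$o1s_snr
    } else 0
    references[[i]] <- perturb_spectrum(ref, offset = offsets[i],
                                        noise_sd = ref_noise,
                                        seed = seeds[i] + 500000L)
  }
  manifest <- data.frame(pH = config$ph_values, true_fraction = fr,
                         applied_offset_eV = offsets, noise_sd = noise_sds,
                         seed = seeds)
  attr(manifest, "true_pka") <- config$true_pka
  list(series = series, references = references,
       reference_center = config$o1s_be, manifest = manifest)
}

draw_bounded_normal <- function(sd, bound) {
  if (sd <= 0) return(0)
  x <- stats::rnorm(1, 0, sd)
  for (i in 1:100) {
    if (abs(x) <= bound) break
    x <- stats::rnorm(1, 0, sd)
  }
  min(bound, max(-bound, x))
}

#' Apply a charging offset and counting noise to a spectrum
#'
#' Shifts the grid by `offset` and adds i.i.d. Gaussian noise of standard
#' deviation `noise_sd` to the intensities; reproducible for a given seed.
#'
#' @param spectrum A [pes_spectrum()].
#' @param offset Energy shift in eV.
#' @param noise_sd Noise standard deviation in intensity units (>= 0).
#' @param seed Optional integer seed.
#' @return The perturbed [pes_spectrum()].
#' @export
perturb_spectrum <- function(spectrum, offset = 0, noise_sd = 0,
                             seed = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  out <- shift_energy(spectrum, offset)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
    out$intensity <- out$intensity +
      stats::rnorm(length(out$intensity), 0, noise_sd)
  }
  out
}

#' Generate a synthetic valence spectrum of an aqueous solution
#'
#' Builds a liquid-water valence background (1b1, split 3a1, 1b2 Gaussians),
#' a sharper gas-phase 1b1 line from the vapor sheath around the liquid jet,
#' and pH-weighted solute features: the protonated solute near its first
#' ionization energy, the deprotonated solute at a lower binding energy, and
#' hydroxide at its fixed literature position with amplitude proportional to
#' `10^(pH - 14)`.
#'
#' The water reference energies and relative solute/water intensity scales
#' are configuration parameters, not constants; the defaults are
#' literature-typical values chosen for the synthetic model only.
#'
#' @param pH Solution pH.
#' @param true_pka Acid dissociation constant governing the solute species
#'   mixing.
#' @param grid Binding-energy grid (eV).
#' @param water_1b1,water_3a1,water_1b2 Liquid-water peak centers (eV);
#'   `water_3a1` has length 2 (split component).
#' @param gas_1b1 Gas-phase water 1b1 center (eV).
#' @param solute_prot_be,solute_deprot_be,hydroxide_be Solute/hydroxide
#'   centers (eV); the hydroxide center is the value that is held fixed when
#'   such spectra are fitted.
#' @param solute_scale Area of the solute features relative to the water
#'   1b1 area (default 0.05).
#' @param hydroxide_scale Hydroxide area per unit `10^(pH - 14)` (default 8).
#' @param sigma_liquid,sigma_gas Gaussian sigmas (eV) for liquid and gas
#'   components.
#' @param noise_sd,seed Passed to [perturb_spectrum()].
#' @return A [pes_spectrum()] with `region = "valence"`.
#' @export
make_valence_spectrum <- function(pH, true_pka = 12.18,
                                  grid = seq(6, 20, by = 0.01),
                                  water_1b1 = 11.33,
                                  water_3a1 = c(13.1, 14.3),
                                  water_1b2 = 17.4,
                                  gas_1b1 = 12.5,
                                  solute_prot_be = 9.1,
                                  solute_deprot_be = 8.5,
                                  hydroxide_be = 9.2,
                                  solute_scale = 0.05,
                                  hydroxide_scale = 8,
                                  sigma_liquid = 0.65,
                                  sigma_gas = 0.18,
                                  noise_sd = 0, seed = NULL) {
  comp <- list(
    gaussian_component(water_1b1, sigma_liquid, 1),
    gaussian_component(water_3a1[1], sigma_liquid * 1.2, 0.55),
    gaussian_component(water_3a1[2], sigma_liquid * 1.2, 0.55),
    gaussian_component(water_1b2, sigma_liquid * 1.3, 1.4),
    gaussian_component(gas_1b1, sigma_gas, 0.12))
  f <- hh_fraction(pH, true_pka)
  if (solute_scale > 0) {
    comp <- c(comp, list(
      gaussian_component(solute_prot_be, sigma_liquid * 0.8,
                         solute_scale * f),
      gaussian_component(solute_deprot_be, sigma_liquid * 0.8,
                         solute_scale * (1 - f))))
  }
  oh_area <- hydroxide_scale * 10^(pH - 14)
  if (oh_area > 0) {
    comp <- c(comp, list(gaussian_component(hydroxide_be, sigma_liquid * 0.8,
                                            oh_area)))
  }
  y <- rep(0, length(grid))
  for (cc in comp) y <- y + gaussian_profile(grid, cc)
  sp <- pes_spectrum(grid, y, pH = pH, region = "valence",
                     label = sprintf("synthetic valence pH %.1f", pH))
  perturb_spectrum(sp, offset = 0, noise_sd = noise_sd, seed = seed)
}
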