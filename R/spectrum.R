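#' Photoelectron spectrum container
#'
#' A `pes_spectrum` holds a strictly increasing binding-energy grid (eV),
#' the corresponding intensities (counts, arbitrary units), and acquisition
#' metadata. It is the common currency passed between all pipeline stages.
#'
#' @param energy Numeric vector of binding energies in eV, strictly
#'   increasing (a descending grid is reversed with a warning).
#' @param intensity Numeric vector of intensities, same length as `energy`;
#'   all values must be finite.
#' @param pH Solution pH at acquisition (`NA` if not applicable).
#' @param region Spectral region, one of `"valence"`, `"C1s"`, `"O1s"`.
#' @param resolution_fwhm Overall experimental energy resolution, FWHM in eV
#'   (>= 0).
#' @param label Free-text label.
#'
#' @return An object of class `pes_spectrum`: a list with elements `energy`,
#'   `intensity` and `meta`.
#' @examples
#' s <- pes_spectrum(seq(288, 296, 0.01),
#'                   gaussian_profile(seq(288, 296, 0.01),
#'                                    gaussian_component(291.5, 0.45, 5)),
#'                   pH = 10, region = "C1s")
#' s
#' @export
pes_spectrum <- function(energy, intensity, pH = NA_real_,
                         region = c("C1s", "valence", "O1s"),
                         resolution_fwhm = 0, label = "") {
  region <- match.arg(region)
  energy <- as.numeric(energy)
  intensity <- as.numeric(intensity)
  if (length(energy) != length(intensity)) {
    stop("`energy` and `intensity` must have equal length", call. = FALSE)
  }
  if (length(energy) < 2L) {
    stop("a spectrum needs at least two grid points", call. = FALSE)
  }
  d <- diff(energy)
  if (all(d < 0)) {
    warning("energy grid is descending; reversing to ascending order")
    energy <- rev(energy)
    intensity <- rev(intensity)
    d <- diff(energy)
  }
  if (any(d <= 0)) {
    stop("energy grid must be strictly monotonic", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("intensities must all be finite", call. = FALSE)
  }
  if (!is.na(resolution_fwhm) && resolution_fwhm < 0) {
    stop("`resolution_fwhm` must be >= 0", call. = FALSE)
  }
  structure(
    list(energy = energy, intensity = intensity,
         meta = list(pH = as.numeric(pH), region = region,
                     resolution_fwhm = as.numeric(resolution_fwhm),
                     label = as.character(label))),
    class = "pes_spectrum"
  )
}

#' @export
print.pes_spectrum <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<pes_spectrum> %s region=%s pH=%s | %d points, %.2f..%.2f eV\n",
    if (nzchar(m$label)) m$label else "(unlabelled)",
    m$region, format(m$pH), length(x$energy),
    min(x$energy), max(x$energy)))
  invisible(x)
}

#' @export
as.data.frame.pes_spectrum <- function(x, ...) {
  data.frame(energy_eV = x$energy, intensity = x$intensity)
}

#' @export
plot.pes_spectrum <- function(x, ..., xlab = "Binding energy (eV)",
                              ylab = "Intensity (arb. units)", type = "l") {
  graphics::plot(x$energy, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Gaussian peak component
#'
#' An area-parameterized Gaussian used both to simulate spectra from
#' vertical ionization energies and as the unit of constrained peak fits.
#'
#' @param center Peak center (binding energy, eV).
#' @param sigma Standard deviation in eV; must be > 0. The empirical
#'   broadening default for solvated-system photoemission is 0.45 eV.
#' @param area Integrated peak area (arbitrary units, >= 0).
#' @return An object of class `gaussian_component`.
#' @examples
#' gaussian_component(291.5, 0.45, 5)
#' @export
gaussian_component <- function(center, sigma, area = 1) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  if (!is.finite(area) || area < 0) {
    stop("`area` must be >= 0", call. = FALSE)
  }
  structure(list(center = as.numeric(center), sigma = as.numeric(sigma),
                 area = as.numeric(area)),
            class = "gaussian_component")
}

#' @export
print.gaussian_component <- function(x, ...) {
  cat(sprintf("<gaussian> center=%.4g eV sigma=%.4g eV area=%.4g\n",
              x$center, x$sigma, x$area))
  invisible(x)
}

#' Evaluate an area-normalized Gaussian profile on an energy grid
#'
#' The profile integrates (trapezoid rule) to the component's `area` when
#' the grid densely spans at least center +/- 6 sigma.
#'
#' @param grid Numeric energy grid in eV (monotonic increasing).
#' @param component A [gaussian_component()].
#' @return Numeric intensity vector, same length as `grid`.
#' @examples
#' g <- seq(-6, 6, 0.01)
#' max(gaussian_profile(g, gaussian_component(0, 1, 1)))  # ~ 1/sqrt(2*pi)
#' @export
gaussian_profile <- function(grid, component) {
  if (!inherits(component, "gaussian_component")) {
    component <- do.call(gaussian_component, as.list(component))
  }
  z <- (grid - component$center) / component$sigma
  component$area * exp(-0.5 * z * z) / (component$sigma * sqrt(2 * pi))
}

#' Peak model: a set of Gaussian components plus fit constraints
#'
#' Constraints are enforced exactly, by reparameterization of the fit
#' (see [fit_peak_model()]), never by penalty terms:
#' * `fixed_center(i, value)` pins component `i`'s center at `value` eV
#'   (e.g. the hydroxide valence feature fixed at its literature binding
#'   energy).
#' * `area_ratio(a, b, ratio)` ties `area(a) = ratio * area(b)` (e.g. the
#'   C1 shoulder vs. the merged C2-C6 feature at 1:5).
#'
#' @param components List of [gaussian_component()] objects (initial values
#'   for fitting, exact values for simulation).
#' @param constraints List of constraints built with [fixed_center()] and
#'   [area_ratio()].
#' @param share_sigma If `TRUE`, all components share a single width
#'   parameter during fitting.
#' @return An object of class `peak_model`.
#' @examples
#' peak_model(
#'   list(gaussian_component(293.0, 0.5, 1), gaussian_component(291.5, 0.5, 5)),
#'   constraints = list(area_ratio(1, 2, 1 / 5)))
#' @export
peak_model <- function(components, constraints = list(), share_sigma = FALSE) {
  if (!length(components)) stop("`components` must be non-empty", call. = FALSE)
  components <- lapply(components, function(cc) {
    if (inherits(cc, "gaussian_component")) cc else do.call(gaussian_component, as.list(cc))
  })
  n <- length(components)
  for (con in constraints) {
    idx <- switch(con$type,
                  fixed_center = con$component,
                  area_ratio = c(con$a, con$b),
                  stop("unknown constraint type: ", con$type, call. = FALSE))
    if (any(idx < 1L | idx > n)) {
      stop("constraint references a component outside 1..", n, call. = FALSE)
    }
    if (con$type == "area_ratio" && (!is.finite(con$ratio) || con$ratio <= 0)) {
      stop("area ratios must be positive", call. = FALSE)
    }
  }
  # area-ratio constraints must form a forest, not a cycle
  master <- seq_len(n)
  for (con in constraints) {
    if (con$type == "area_ratio") master[con$a] <- con$b
  }
  for (i in seq_len(n)) {
    seen <- i
    while (master[seen[length(seen)]] != seen[length(seen)]) {
      nxt <- master[seen[length(seen)]]
      if (nxt %in% seen) {
        stop("circular area-ratio constraints", call. = FALSE)
      }
      seen <- c(seen, nxt)
    }
  }
  structure(list(components = components, constraints = constraints,
                 share_sigma = isTRUE(share_sigma)),
            class = "peak_model")
}

#' @rdname peak_model
#' @param component,a,b Component indices into `components`.
#' @param value Fixed center value in eV.
#' @param ratio Positive area ratio `area(a)/area(b)`.
#' @export
fixed_center <- function(component, value) {
  list(type = "fixed_center", component = as.integer(component),
       value = as.numeric(value))
}

#' @rdname peak_model
#' @export
area_ratio <- function(a, b, ratio) {
  list(type = "area_ratio", a = as.integer(a), b = as.integer(b),
       ratio = as.numeric(ratio))
}

#' Vertical ionization energy table
#'
#' Per-site (or per-orbital) vertical ionization energies for one species,
#' the input to forward spectrum simulation.
#'
#' @param species Species label (recycled).
#' @param site Site or orbital labels, unique within a species.
#' @param vie Vertical ionization energies in eV, all positive.
#' @return A `data.frame` with columns `species`, `site`, `vie_eV` and class
#'   `vie_table`.
#' @examples
#' vie_table("glucose0", c("HOMO", "HOMO-1", "HOMO-2"), c(9.09, 9.40, 9.66))
#' @export
vie_table <- function(species, site, vie) {
  vie <- as.numeric(vie)
  if (!length(vie)) stop("`vie` must be non-empty", call. = FALSE)
  if (any(!is.finite(vie) | vie <= 0)) {
    stop("all VIE values must be positive", call. = FALSE)
  }
  df <- data.frame(species = as.character(species), site = as.character(site),
                   vie_eV = vie, stringsAsFactors = FALSE)
  dup <- duplicated(df[c("species", "site")])
  if (any(dup)) {
    stop("site labels must be unique within a species: ",
         paste(df$site[dup], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("vie_table", "data.frame")
  df
}

#' Compose per-electron VIEs from a base VIE and excitation energies
#'
#' The delta-SCF first ionization energy is extended to deeper electrons by
#' adding excitation energies into the singly occupied orbital of the cation:
#' `VIE_i = VIE_1 + E_exc,i`.
#'
#' @param base_vie First vertical ionization energy (eV, > 0).
#' @param excitations Numeric vector of excitation energies (eV, >= 0);
#'   may be empty.
#' @return Ascending numeric vector `c(base_vie, base_vie + excitations)`.
#' @examples
#' compose_vies(7.95, c(0.92, 1.49))  # 7.95 8.87 9.44
#' @export
compose_vies <- function(base_vie, excitations = numeric()) {
  if (!is.finite(base_vie) || base_vie <= 0) {
    stop("`base_vie` must be positive", call. = FALSE)
  }
  excitations <- as.numeric(excitations)
  if (any(!is.finite(excitations) | excitations < 0)) {
    stop("excitation energies must be >= 0", call. = FALSE)
  }
  sort(c(base_vie, base_vie + excitations))
}

#' Simulate a spectrum from a VIE table by empirical Gaussian broadening
#'
#' Each ionization energy contributes one unit-area Gaussian of standard
#' deviation `sigma` centered at its VIE; the spectrum is their sum, so the
#' total area equals the number of entries.
#'
#' @param vies A [vie_table()] or a numeric vector of VIEs in eV.
#' @param sigma Gaussian standard deviation in eV (default 0.45, the
#'   empirical inhomogeneous-broadening width for solvated systems).
#' @param grid Energy grid in eV; defaults to `min(vie) - 3*sigma` ..
#'   `max(vie) + 3*sigma` at 0.01 eV spacing.
#' @param instrument_fwhm Optional instrumental resolution (FWHM, eV) folded
#'   in quadrature with `sigma`.
#' @param region,pH,label Metadata passed to [pes_spectrum()].
#' @return A [pes_spectrum()].
#' @examples
#' simulate_spectrum_from_vies(c(292.9, rep(291.5, 5)), sigma = 0.45)
#' @export
simulate_spectrum_from_vies <- function(vies, sigma = 0.45, grid = NULL,
                                        instrument_fwhm = 0,
                                        region = "C1s", pH = NA_real_,
                                        label = "") {
  v <- if (inherits(vies, "vie_table")) vies$vie_eV else as.numeric(vies)
  if (!length(v)) stop("VIE table is empty", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  sig <- combine_sigma(sigma, instrument_fwhm)
  if (is.null(grid)) {
    grid <- seq(min(v) - 3 * sig, max(v) + 3 * sig, by = 0.01)
  }
  intensity <- rep(0, length(grid))
  for (vi in v) {
    intensity <- intensity +
      gaussian_profile(grid, gaussian_component(vi, sig, 1))
  }
  pes_spectrum(grid, intensity, pH = pH, region = region,
               resolution_fwhm = instrument_fwhm, label = label)
}

# Intrinsic sigma and instrumental FWHM added in quadrature; the FWHM of a
# Gaussian is 2*sqrt(2*log(2)) * sigma ~ 2.3548 * sigma.
combine_sigma <- function(sigma, instrument_fwhm = 0) {
  if (is.null(instrument_fwhm) || !is.finite(instrument_fwhm) ||
      instrument_fwhm <= 0) {
    return(sigma)
  }
  sqrt(sigma^2 + (instrument_fwhm / (2 * sqrt(2 * log(2))))^2)
}

#' Trapezoid-rule integral of a spectrum over a window
#'
#' @param spectrum A [pes_spectrum()].
#' @param window Length-2 numeric `c(lo, hi)` in eV, or `NULL` for the full
#'   grid.
#' @return The integral (intensity x eV).
#' @export
spectrum_integral <- function(spectrum, window = NULL) {
  x <- spectrum$energy
  y <- spectrum$intensity
  if (!is.null(window)) {
    window <- sort(as.numeric(window))
    keep <- x >= window[1] & x <= window[2]
    if (sum(keep) < 2L) {
      stop("integration window contains fewer than two grid points",
           call. = FALSE)
    }
    x <- x[keep]
    y <- y[keep]
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area-normalize a spectrum over a window
#'
#' Scales intensities so the trapezoid integral over `window` equals 1,
#' preserving the spectral shape. Used before basis-curve unmixing so that
#' the mixing coefficient is a species fraction.
#'
#' @inheritParams spectrum_integral
#' @return The rescaled [pes_spectrum()].
#' @export
area_normalize <- function(spectrum, window = NULL) {
  a <- spectrum_integral(spectrum, window)
  if (!is.finite(a) || a <= 0) {
    stop("cannot area-normalize: integral over window is not positive",
         call. = FALSE)
  }
  spectrum$intensity <- spectrum$intensity / a
  spectrum
}

#' Shift a spectrum along the binding-energy axis
#'
#' Translates the grid by `delta` eV; intensities are untouched. Used to
#' overlap the main spectral feature across spectra prior to fitting and to
#' model charging offsets.
#'
#' @param spectrum A [pes_spectrum()].
#' @param delta Energy shift in eV (positive moves features to higher BE).
#' @return The shifted [pes_spectrum()].
#' @export
shift_energy <- function(spectrum, delta) {
  spectrum$energy <- spectrum$energy + delta
  spectrum
}

#' Calibrate a spectrum to a reference peak position
#'
#' Locates the dominant peak inside `search_window` with a single-Gaussian
#' least-squares fit and shifts the spectrum so the fitted center lands at
#' `reference_center`. This is how liquid-jet spectra are put on an absolute
#' binding-energy scale (valence spectra against the water 1b1 line, core
#' levels against the water O 1s line), cancelling pH-dependent surface
#' charging.
#'
#' @param spectrum A [pes_spectrum()].
#' @param reference_center Literature binding energy of the reference peak
#'   (eV).
#' @param search_window Length-2 numeric window (eV) expected to contain
#'   exactly one dominant reference peak.
#' @param min_snr Minimum ratio of in-window peak height above baseline to
#'   the noise scale; below it calibration aborts.
#' @return A list with `spectrum` (the calibrated [pes_spectrum()]),
#'   `detected_offset` (eV, the shift that was removed, i.e. observed minus
#'   reference center) and `fitted_center` (eV).
#' @export
calibrate_to_reference <- function(spectrum, reference_center, search_window,
                                   min_snr = 5) {
  search_window <- sort(as.numeric(search_window))
  keep <- spectrum$energy >= search_window[1] &
    spectrum$energy <= search_window[2]
  if (sum(keep) < 5L) {
    stop("search window contains too few grid points", call. = FALSE)
  }
  x <- spectrum$energy[keep]
  y <- spectrum$intensity[keep]
  base <- stats::median(y)
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (noise <= 0) noise <- .Machine$double.eps
  peak_height <- max(y) - base
  if (peak_height < min_snr * noise) {
    stop("calibration failure: no peak above the noise floor in the search ",
         "window", call. = FALSE)
  }
  fitted <- fit_single_gaussian(x, y)
  if (!fitted$converged || fitted$center < search_window[1] ||
      fitted$center > search_window[2]) {
    stop("calibration failure: reference-peak fit did not converge inside ",
         "the search window", call. = FALSE)
  }
  offset <- fitted$center - reference_center
  list(spectrum = shift_energy(spectrum, -offset),
       detected_offset = offset, fitted_center = fitted$center)
}

# Single Gaussian + constant baseline fit, used for peak location during
# calibration/alignment. Returns center, sigma, area, converged.
fit_single_gaussian <- function(x, y) {
  i0 <- which.max(y)
  c0 <- x[i0]
  b0 <- min(y)
  a0 <- max(y) - b0
  s0 <- max(0.2, diff(range(x)) / 10)
  res_fn <- function(p) {
    p["amp"] * exp(-0.5 * ((x - p["center"]) / p["sigma"])^2) + p["base"] - y
  }
  fit <- minpack.lm::nls.lm(
    par = c(center = c0, sigma = s0, amp = a0, base = b0),
    lower = c(min(x), 0.02, 0, -Inf),
    upper = c(max(x), diff(range(x)), Inf, Inf),
    fn = res_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  list(center = unname(p["center"]), sigma = unname(p["sigma"]),
       area = unname(p["amp"] * p["sigma"] * sqrt(2 * pi)),
       converged = fit$info %in% 1:4)
}

#' Interpolate a spectrum onto a new energy grid
#'
#' Linear interpolation; outside the source grid the intensity is taken as
#' the nearest edge value (spectra are expected to decay to baseline at the
#' window edges).
#'
#' @param spectrum A [pes_spectrum()].
#' @param grid Target energy grid (eV).
#' @return A [pes_spectrum()] on `grid`.
#' @export
interpolate_spectrum <- function(spectrum, grid) {
  yi <- stats::approx(spectrum$energy, spectrum$intensity, xout = grid,
                      rule = 2)$y
  out <- spectrum
  out$energy <- as.numeric(grid)
  out$intensity <- yi
  out
}
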