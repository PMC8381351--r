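# Noiseless pure-species C 1s envelopes used as known ground truth across
# the decomposition and titration tests. Widths combine the intrinsic
# 0.45 eV broadening with the 0.28 eV FWHM instrumental resolution.
total_sigma <- function(intrinsic = 0.45, fwhm = 0.28) {
  sqrt(intrinsic^2 + (fwhm / (2 * sqrt(2 * log(2))))^2)
}

c1s_species_spectrum <- function(centers, areas = c(1, 5),
                                 sigma = total_sigma(),
                                 grid = seq(287, 297, by = 0.01),
                                 pH = NA_real_) {
  y <- rep(0, length(grid))
  for (k in seq_along(centers)) {
    y <- y + gaussian_profile(grid, gaussian_component(centers[k], sigma,
                                                       areas[k]))
  }
  pes_spectrum(grid, y, pH = pH, region = "C1s", resolution_fwhm = 0.28)
}

protonated_c1s <- function(...) c1s_species_spectrum(c(292.9, 291.5), ...)
deprotonated_c1s <- function(...) c1s_species_spectrum(c(292.5, 291.5), ...)

mix_spectra <- function(a, b, r) {
  out <- a
  out$intensity <- r * a$intensity + (1 - r) * b$intensity
  out
}
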