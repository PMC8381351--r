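---
title: "Photoemission spectroscopy titration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photoemission spectroscopy titration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectitr)
```

## The problem

A weak polyprotic acid in aqueous solution — glucose is the motivating
system — changes its electronic structure when a hydroxyl group
deprotonates. Liquid-jet photoelectron spectroscopy resolves this
site-specifically: the C 1s binding energy of the carbon bearing the
deprotonated group drops by several hundred meV, while the other carbon
sites barely move. Recording C 1s spectra across a pH series therefore
yields a *photoemission spectroscopy titration*: each spectrum is a
two-species mixture whose protonated fraction follows the acid-base
equilibrium, and decomposing the series yields the acid dissociation
constant together with the identity of the deprotonation site.

`spectitr` implements this analysis end to end: spectrum containers and
calibration, forward simulation from vertical ionization energies,
constrained Gaussian peak fitting, two-basis unmixing, the titration fit,
and the thermodynamic-cycle arithmetic that converts computed free
energies into pKa values. A synthetic-data generator with known ground
truth makes every stage testable without measured data.

## Spectral model

A spectrum is a strictly increasing binding-energy grid (eV) with
intensities and acquisition metadata (`pes_spectrum`). Peaks are
area-parameterized Gaussians: inhomogeneous (environmental) broadening
dominates solvated-system photoemission, so Gaussian — not Voigt —
profiles are appropriate; the C 1s lifetime width (~0.1 eV) is an order
of magnitude below the Gaussian widths and is neglected.

Forward simulation from a table of vertical ionization energies uses the
empirical broadening scheme: one unit-area Gaussian of standard
deviation $\sigma = 0.45$ eV per ionization energy. Instrumental
resolution (given as FWHM; 0.28 eV for the core-level setting, 0.23 eV
for valence) is folded in quadrature,
$\sigma_\mathrm{tot} = \sqrt{\sigma^2 + (\mathrm{FWHM}/2.3548)^2}$,
treating both broadenings as independent Gaussians.

Numerical conventions: uniform grids with 0.01 eV spacing (well below
every stated resolution); trapezoid-rule integrals; the energy axis is
always binding energy, increasing.

## Calibration

Liquid-jet spectra shift globally by up to a few hundred meV with
solution conductivity and pH ("charging"). The remedy is calibration
against a solvent reference line measured from the same solution — the
water 1b$_1$ level for valence spectra, the water O 1s level for core
spectra. `calibrate_to_reference()` locates the reference line by a
single-Gaussian fit inside a search window and shifts the spectrum so
the fitted center lands at the reference energy. The reference energies
are configuration parameters, not package constants.

Calibration against an *external* line matters statistically, not just
practically: if charging offsets must instead be estimated from the
analyte spectra themselves (by overlapping the main feature), part of
the composition information is spent on alignment. Both routes are
implemented in `run_titration()`; external calibration is used whenever
reference spectra are supplied.

## Constrained peak fitting

`fit_peak_model()` fits a sum of Gaussians by bounded
Levenberg–Marquardt least squares (via `minpack.lm`). Constraints are
enforced by reparameterization — constrained quantities are eliminated
from the parameter vector and reconstructed from their masters — so they
hold exactly at every optimizer step, never approximately via penalties.
Two constraint types cover the analyses here:

* `fixed_center`: e.g. the hydroxide valence feature pinned at its
  literature binding energy while the nearby solute feature floats;
* `area_ratio`: e.g. the C1 shoulder tied to one fifth of the merged
  C2–C6 feature, encoding one unique site against five overlapping ones.
  A six-component per-site fit is deliberately not offered: with five
  near-degenerate components it is not unique and its errors are
  uninformative.

Bounds encode physical plausibility: widths in [0.05, 2] eV, centers
inside the fit window, areas non-negative. Uncertainties come from the
covariance of the converged fit; fixed parameters report zero
uncertainty, and tied areas inherit the master's scaled uncertainty.
Whether the two components share a width is a fit option
(`share_sigma`), as is the window.

## Two-basis unmixing

The titration's central operation expresses an intermediate-pH spectrum
as `ratio * basis_low + (1 - ratio) * basis_high`, with the
representative low- and high-pH spectra as basis curves. All spectra are
interpolated to a common grid and area-normalized over a common window
(by default the signal support of the basis envelopes — the flanks
contribute only noise). The estimator in `fit_two_basis()` is built for
basis curves that are *measured spectra*, with the same counting noise
as the target:

* **Scale.** Rather than trusting each spectrum's area integral (whose
  noise couples into the ratio amplified by the overlap geometry), the
  target's scale is measured with the matched functional $w$ satisfying
  $\langle A, w\rangle = \langle B, w\rangle = 1$, which is
  noise-optimal for any mixture of the two bases.
* **Debiasing.** Noise inflates $\lVert A - B\rVert^2$, shrinking every
  ratio toward 0.5 and flattening the titration curve. The normal
  equations are debiased by the expected noise contribution, with each
  spectrum's noise variance estimated robustly from its second
  differences on its own grid and propagated analytically through
  interpolation and smoothing.
* **Smoothing.** A shared 0.1 eV boxcar is applied to target and bases.
  Being linear and identical for all three, it leaves exact mixtures
  exact while damping the marginal noise terms.
* **Alignment.** With `align = TRUE` the main features are overlapped
  prior to fitting: coarse single-Gaussian peak location, then a joint
  refinement of the target's shift with the mixing ratio (a single-peak
  center is pulled by the shoulder in a composition-dependent way; the
  joint fit is not). The relative offset of the two basis curves is
  refined once per series with an estimator linear in the unmixing
  residuals, excluding the basis members themselves.
* **Reporting.** The bounded `ratio` lies in [0, 1] with values pinned at
  a bound flagged; the unbounded `ratio_raw` is also returned and is the
  right input for downstream fitting, because clipping censors the noise
  distribution near the endpoints.

## Titration model

The protonated fraction follows the rearranged Henderson–Hasselbalch
relation
$$f(\mathrm{pH}) = \frac{1}{1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a}},$$
so $f(\mathrm{p}K_a) = 1/2$, $f$ decreases strictly with pH, and
$f(\mathrm{p}K_a + \delta) + f(\mathrm{p}K_a - \delta) = 1$. Only the
pKa is free by default; the asymptotes are fixed at 0 and 1 (a two-state
mixture). A free-asymptote variant exists for series whose high-pH end
fails to plateau because a second deprotonation begins, but it is
substantially less precise on narrow pH spans and is not the default.

Because the basis curves are recorded at finite pH values, they contain
residual amounts of the other species; at a first pKa near 12.2, a pH 13
"deprotonated" basis is still ~13% protonated. The unmixing ratio is
therefore an *apparent* fraction, and `fit_pka()` fits the
endpoint-corrected model
$$r(\mathrm{pH}) = \frac{f(\mathrm{pH}) - f(\mathrm{pH}_{hi})}
  {f(\mathrm{pH}_{lo}) - f(\mathrm{pH}_{hi})}$$
when the basis pH values are known — still with a single free parameter.
Under this model the basis spectra's own points are pinned at exactly 1
and 0 for any pKa; they carry no information and are excluded from the
fit.

Noise in the shared basis curves perturbs every ratio coherently,
by $-r\,a - (1-r)\,b$ with draws $a, b$ common to the whole curve. The
fit therefore uses generalized least squares with covariance
$\mathrm{diag}(s_i^2) + s_a^2\, LL' + s_b^2\, HH'$ ($L_i = r_i$,
$H_i = 1 - r_i$), with all scales estimated from the data by the
unmixing stage. A diagnostic flag (`pka2_flag`) is raised when the
highest-pH point deviates from the fitted curve by more than three
residual standard deviations — the signature of a second deprotonation
contaminating the high-pH end, which is outside the one-site model.

## Thermodynamic cycle and populations

For computed acidities, the aqueous deprotonation free energy combines
gas-phase and solvation terms,
$\Delta G_{aq} = \Delta G_{g} + \Delta G_{solv,prod} - \Delta G_{solv,react}$,
with the solvated proton entering the product side (literature value
$-265.9$ kcal/mol, exposed as `proton_solvation_kcal`). The standard
relation $\mathrm{p}K_a = \Delta G_{aq} / (RT \ln 10)$ converts to a
pKa; an optional additive term accommodates gas-phase standard-state
conventions (1 atm vs 1 M), defaulting to zero. Boltzmann populations of
higher-energy forms are reported relative to the reference minimum,
$\exp(-\Delta E / RT)$, not normalized over a conformer ensemble —
matching how such bounds are quoted. Unit conversions use CODATA
factors ($R = 8.31446$ J mol$^{-1}$ K$^{-1}$, 1 eV = 96.485 kJ/mol,
1 kcal = 4.184 kJ) and are exact under round trips.

## The synthetic-data generator

`make_c1s_series()` emulates the measurement with known ground truth:

* Species envelopes: protonated C 1s components at 292.9 and 291.5 eV,
  deprotonated at 292.5 and 291.5 eV, shoulder-to-main area ratio 1:5,
  intrinsic $\sigma$ 0.45 eV combined with 0.28 eV FWHM instrumental
  resolution.
* Mixing: the protonated fraction at each pH follows `hh_fraction()`
  with a default ground-truth pKa of 12.18; the default series spans
  pH 10–13 in 0.5 steps.
* Charging: one offset per acquisition, drawn from N(0, 0.1 eV)
  truncated at ±0.3 eV — matching the few-hundred-meV shifts seen in
  practice.
* Noise: additive Gaussian with standard deviation set by a target
  signal-to-noise ratio at the main-peak maximum (default 50), on the
  0.01 eV grid. A Poisson model at matching peak counts is statistically
  equivalent at these levels.
* Calibration channel: each acquisition also yields a solvent O 1s
  reference spectrum carrying the *same* charging offset, with SNR 200 —
  reflecting that the ~55 M solvent line towers over a 1 M solute
  signal (the O 1s reference energy, default 538.1 eV, is a config
  parameter and only needs to be self-consistent for synthetic data).
* Determinism: every random draw derives from the config seed and is
  recorded in the manifest.

The valence generator (`make_valence_spectrum()`) adds a liquid-water
background (1b$_1$, split 3a$_1$, 1b$_2$), a sharper gas-phase 1b$_1$
line near 12.5 eV from the vapor sheath, and pH-weighted solute features
(protonated near 9.1 eV, deprotonated at 8.5 eV, hydroxide at 9.2 eV
scaled with $10^{\mathrm{pH}-14}$). The relative solute-to-water
intensity scales are order-of-magnitude choices exposed as parameters.

What the generator does *not* emulate: inelastic backgrounds,
cross-section energy dependence, vibrational structure, drifts within an
acquisition, or correlated detector noise. Passing tests on synthetic
data therefore demonstrate the correctness and statistical efficiency of
the analysis under the stated noise model, not robustness to every
artifact of real beamline data.

## Statistical design notes

A titration whose basis curves come from the series itself operates
close to an information limit: with unknown species profiles, the
composition information lives in the part of the Henderson–Hasselbalch
sensitivity orthogonal to affine distortions of the curve, and at
SNR 50 on seven pH points the achievable pKa standard deviation is a
few times $10^{-2}$. Three design choices matter most near that limit,
and each is motivated above: debiasing (removes the curve-flattening
attenuation), GLS with the basis-noise modes (discounts the coherent
distortions), and external calibration (keeps alignment from consuming
composition information). Problem sizes in the tests — grids of ~1000
points, series of 7 spectra, Monte-Carlo ensembles of 100–500 seeds —
were chosen so the whole suite completes in seconds while estimating
recovery rates to a percent or two.

## Worked example

```{r example}
cfg <- synthetic_config(seed = 421)
out <- make_c1s_series(cfg)
res <- run_titration(out$series, references = out$references,
                     reference_center = out$reference_center)
res
```

The fitted pKa lands within a few hundredths of the generator's ground
truth of `r cfg$true_pka`; `plot(res)` shows the titration curve through
the per-pH protonated fractions.

## Known limitations

* One-site model only: the second acidity constant is flagged when it
  intrudes, never fitted.
* Gaussian peaks only: no Voigt profiles, Shirley backgrounds, or
  transmission corrections.
* The generator's defaults describe one specific measurement scenario;
  other instruments and solutes require re-parameterization.
* The unmixing assumes the two basis spectra differ beyond their noise;
  it refuses (with an informative error) when they do not.
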