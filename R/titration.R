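#' Protonated fraction from the rearranged Henderson-Hasselbalch relation
#'
#' For a one-site acid-base equilibrium the fraction of the protonated
#' species at a given pH is
#' \deqn{f(\mathrm{pH}) = \frac{1}{1 + 10^{\mathrm{pH} - \mathrm{p}K_a}}}
#' so that `f(pKa) = 0.5`, `f` is strictly decreasing in pH, and
#' `f(pKa + d) + f(pKa - d) = 1`.
#'
#' @param pH Numeric pH value(s).
#' @param pka Acid dissociation constant (pKa).
#' @return Protonated fraction(s) in (0, 1).
#' @examples
#' hh_fraction(12.18, 12.18)       # 0.5
#' hh_fraction(10.18, 12.18)       # ~ 0.99
#' @export
hh_fraction <- function(pH, pka) {
  1 / (1 + 10^(pH - pka))
}

#' Fit a pKa to titration points
#'
#' Weighted nonlinear least squares of the rearranged Henderson-Hasselbalch
#' fraction [hh_fraction()] to observed (pH, protonated-fraction) pairs.
#' Only the pKa is free; the asymptotes are fixed at 0 and 1 (a two-state
#' mixture). Weights are inverse-variance from the ratio uncertainties when
#' supplied and positive, else uniform.
#'
#' When the "pure" basis spectra of a photoemission titration are
#' themselves recorded at finite pH values — as when the lowest- and
#' highest-pH members of the series serve as basis curves — they contain
#' residual amounts of the other species, and the unmixing ratio is an
#' *apparent* fraction relative to those impure endmembers. Supplying
#' `basis_ph = c(pH_low, pH_high)` fits the endpoint-corrected model
#' \deqn{r(\mathrm{pH}) = \frac{f(\mathrm{pH}) - f(\mathrm{pH}_{hi})}
#'   {f(\mathrm{pH}_{lo}) - f(\mathrm{pH}_{hi})}}
#' with `f` the Henderson-Hasselbalch fraction, still with the pKa as the
#' only free parameter; `basis_ph = NULL` fits the plain fraction.
#'
#' A diagnostic flag is raised when the highest-pH point deviates from the
#' fitted curve by more than 3 residual standard deviations — the signature
#' of a second deprotonation equilibrium contaminating the high-pH end.
#'
#' @param pH Numeric vector of pH values.
#' @param ratio Protonated fractions in [0, 1] (e.g. from [fit_two_basis()]).
#' @param ratio_uncertainty Optional per-point standard errors.
#' @param basis_ph Optional length-2 numeric `c(pH_low, pH_high)` at which
#'   the basis spectra were recorded, enabling the endpoint-impurity
#'   correction described above.
#' @param free_asymptotes If `TRUE`, fit `alpha + beta * r(pH)` with free
#'   affine nuisance parameters instead of pinning the asymptotes at 0/1
#'   (requires >= 4 points). This variant accommodates a high-pH end that
#'   fails to plateau because a second deprotonation begins, at the price
#'   of substantially less precision when the points span a narrow pH
#'   range.
#' @param basis_noise_sd Optional length-2 `c(sd_low, sd_high)`: 1-sigma
#'   projections of the two basis curves' noise onto the unmixing
#'   direction (`noise_projections` of [fit_two_basis()]). When measured
#'   spectra serve as basis curves, their noise perturbs every ratio
#'   coherently by `-r*a - (1-r)*b` with shared draws `a`, `b`; supplying
#'   these sds turns the fit into generalized least squares with
#'   covariance `diag(s_i^2) + sd_low^2 L L' + sd_high^2 H H'`
#'   (`L = r`, `H = 1 - r`), which discounts exactly those curve-wide
#'   distortion modes. `ratio_uncertainty` then supplies the independent
#'   per-point sds `s_i`.
#' @return A `titration_result`: list with `pka`, `pka_uncertainty`,
#'   `points` (data.frame of inputs and fitted fractions), `fitted_curve`
#'   (function pH -> fraction), `extrapolation` (TRUE when points do not
#'   bracket fraction 0.5) and `pka2_flag`.
#' @examples
#' ph <- seq(10.5, 12.5, 0.5)
#' fit_pka(ph, hh_fraction(ph, 12.18))
#' @export
fit_pka <- function(pH, ratio, ratio_uncertainty = NULL, basis_ph = NULL,
                    free_asymptotes = FALSE, basis_noise_sd = NULL) {
  if (is.data.frame(pH)) {
    df <- pH
    ratio <- df$ratio
    ratio_uncertainty <- df$ratio_uncertainty
    pH <- df$pH
  }
  pH <- as.numeric(pH)
  ratio <- as.numeric(ratio)
  if (length(pH) != length(ratio)) {
    stop("`pH` and `ratio` must have equal length", call. = FALSE)
  }
  if (length(pH) < 2L) {
    stop("insufficient data: at least two titration points are required",
         call. = FALSE)
  }
  # unclipped unmixing estimates may overshoot the physical range by noise;
  # gross violations still indicate wrong input
  if (any(ratio < -0.5 | ratio > 1.5)) {
    stop("fractions must lie in (or scatter narrowly around) [0, 1]",
         call. = FALSE)
  }
  eps <- 1e-6
  if (all(ratio <= eps) || all(ratio >= 1 - eps)) {
    stop("pKa is unidentifiable: all points are at the same asymptote",
         call. = FALSE)
  }
  w <- rep(1, length(pH))
  if (!is.null(ratio_uncertainty) && all(is.finite(ratio_uncertainty)) &&
      all(ratio_uncertainty > 0)) {
    w <- 1 / ratio_uncertainty^2
    w <- w / mean(w)
  }
  sw <- sqrt(w)
  if (!is.null(basis_ph)) {
    basis_ph <- sort(as.numeric(basis_ph))
    if (length(basis_ph) != 2L || any(!is.finite(basis_ph))) {
      stop("`basis_ph` must be two finite pH values", call. = FALSE)
    }
  }
  predict_ratio <- function(pH, pka) {
    f <- hh_fraction(pH, pka)
    if (is.null(basis_ph)) return(f)
    f_lo <- hh_fraction(basis_ph[1], pka)
    f_hi <- hh_fraction(basis_ph[2], pka)
    (f - f_hi) / (f_lo - f_hi)
  }
  start <- pH[which.min(abs(ratio - 0.5))]
  if (free_asymptotes) {
    if (length(pH) < 4L) {
      stop("free-asymptote fit needs at least four titration points",
           call. = FALSE)
    }
    par0 <- c(pka = start, alpha = 0, beta = 1)
    fit <- minpack.lm::nls.lm(
      par = par0,
      fn = function(p) {
        sw * (p[["alpha"]] + p[["beta"]] * predict_ratio(pH, p[["pka"]]) -
                ratio)
      },
      control = minpack.lm::nls.lm.control(maxiter = 500))
    n_par <- 3L
  } else {
    fit <- minpack.lm::nls.lm(
      par = c(pka = start),
      fn = function(p) sw * (predict_ratio(pH, p[["pka"]]) - ratio),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    n_par <- 1L
  }
  pka <- unname(fit$par[["pka"]])

  if (!is.null(basis_noise_sd) && !free_asymptotes) {
    # GLS refit: whiten with the covariance of the shared basis-noise
    # modes evaluated at the first-pass estimate, then re-minimize.
    basis_noise_sd <- as.numeric(basis_noise_sd)
    s_i <- if (!is.null(ratio_uncertainty) &&
               all(is.finite(ratio_uncertainty)) &&
               all(ratio_uncertainty > 0)) {
      as.numeric(ratio_uncertainty)
    } else {
      rep(max(basis_noise_sd, 1e-3), length(pH))
    }
    L <- predict_ratio(pH, pka)
    H <- 1 - L
    Sigma <- diag(s_i^2, length(pH)) +
      basis_noise_sd[1]^2 * outer(L, L) + basis_noise_sd[2]^2 * outer(H, H)
    Rc <- chol(Sigma)
    fit <- minpack.lm::nls.lm(
      par = c(pka = pka),
      fn = function(p) {
        backsolve(Rc, predict_ratio(pH, p[["pka"]]) - ratio,
                  transpose = TRUE)
      },
      control = minpack.lm::nls.lm.control(maxiter = 200))
    pka <- unname(fit$par[["pka"]])
  }

  rss <- sum(fit$fvec^2)
  dof <- max(1L, length(pH) - n_par)
  pka_se <- NA_real_
  hv <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(hv, "try-error") && is.finite(hv[1, 1]) && hv[1, 1] > 0) {
    pka_se <- sqrt(2 * rss / dof * hv[1, 1])
  }

  fitted <- if (free_asymptotes) {
    unname(fit$par[["alpha"]]) +
      unname(fit$par[["beta"]]) * predict_ratio(pH, pka)
  } else {
    predict_ratio(pH, pka)
  }
  resid <- ratio - fitted
  i_hi <- which.max(pH)
  # scale from the OTHER residuals (the suspect point must not inflate its
  # own yardstick), floored so a perfect noiseless fit never flags
  sdres <- stats::sd(resid[-i_hi])
  pka2_flag <- is.finite(sdres) &&
    abs(resid[i_hi]) > 3 * max(sdres, 0.01)
  extrapolation <- !(any(ratio > 0.5) && any(ratio < 0.5)) || length(pH) < 3L

  structure(
    list(pka = pka, pka_uncertainty = pka_se,
         points = data.frame(pH = pH, ratio = ratio, fitted = fitted,
                             weight = w),
         fitted_curve = local({
           pka_fixed <- pka
           function(pH) hh_fraction(pH, pka_fixed)
         }),
         extrapolation = extrapolation, pka2_flag = pka2_flag,
         basis_ph = basis_ph,
         free_asymptotes = free_asymptotes,
         asymptotes = if (free_asymptotes)
           c(alpha = unname(fit$par[["alpha"]]),
             beta = unname(fit$par[["beta"]])) else c(alpha = 0, beta = 1),
         converged = fit$info %in% 1:4),
    class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("<titration_result> pKa = %.3f +/- %.3f (%d points)%s%s\n",
              x$pka, x$pka_uncertainty, nrow(x$points),
              if (x$extrapolation) " [extrapolated]" else "",
              if (x$pka2_flag) " [high-pH deviation: possible second deprotonation]" else ""))
  invisible(x)
}

#' @export
plot.titration_result <- function(x, ..., xlab = "pH",
                                  ylab = "Protonated fraction") {
  graphics::plot(x$points$pH, x$points$ratio, xlab = xlab, ylab = ylab,
                 ylim = c(0, 1), pch = 19, ...)
  ph_grid <- seq(min(x$points$pH) - 0.5, max(x$points$pH) + 0.5, length.out = 200)
  graphics::lines(ph_grid, x$fitted_curve(ph_grid))
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$pka, lty = 3)
  invisible(x)
}

#' Photoemission-spectroscopy titration: spectra to pKa
#'
#' Runs the full spectro-titration analysis: each spectrum in the series is
#' area-normalized, aligned so its main feature overlaps the basis curves,
#' and unmixed against the two pure-species basis spectra
#' ([fit_two_basis()]); the resulting per-pH protonated fractions are then
#' fed to [fit_pka()].
#'
#' @param series A list of [pes_spectrum()] objects with `meta$pH` set, or a
#'   list of `list(pH =, spectrum =)` pairs. Sorted by pH internally.
#' @param references Optional list of reference spectra (e.g. the solvent
#'   O 1s line measured from each solution), parallel to `series`. When
#'   supplied together with `reference_center`, every spectrum is
#'   calibrated first — its charging offset is measured on the reference
#'   line by [calibrate_to_reference()] and removed — and no main-feature
#'   self-alignment is performed afterwards. External calibration is
#'   preferable whenever available: estimating the offsets from the
#'   analyte spectra themselves consumes part of the composition
#'   information.
#' @param reference_center Binding energy of the reference line (eV).
#' @param basis_low,basis_high Basis spectra for the unmixing (protonated /
#'   deprotonated endmembers): either [pes_spectrum()] objects, a single
#'   numeric pH designating a member of the series, or `NULL` to use the
#'   lowest- and highest-pH members.
#' @param window Normalization/unmixing window (eV); default from the series.
#' @param align_window Main-feature alignment window passed to
#'   [fit_two_basis()].
#' @param align Logical, overlap the main feature of every spectrum with the
#'   low-pH basis before unmixing.
#' @param correct_basis_purity When the basis spectra carry finite pH
#'   metadata, fit the endpoint-impurity-corrected titration model (see
#'   [fit_pka()]'s `basis_ph`). Default `TRUE`.
#' @param asymptotes `"fixed"` (the default two-state model) pins the
#'   titration curve at 0/1; `"free"` fits affine nuisance parameters (see
#'   [fit_pka()]), useful when the high-pH end visibly fails to plateau.
#' @param drop_basis_points Exclude the basis spectra's own points from the
#'   pKa fit. When the basis curves are drawn from the series itself and
#'   the purity correction is active, those points are pinned at exactly
#'   1/0 for any pKa and carry no information, so they are dropped
#'   automatically; this flag forces dropping for user-supplied bases too.
#' @return A `titration_result` (see [fit_pka()]) with an extra `unmixing`
#'   element holding the per-pH [fit_two_basis()] results.
#' @export
run_titration <- function(series, basis_low = NULL, basis_high = NULL,
                          references = NULL, reference_center = NULL,
                          window = NULL, align_window = 1.0, align = TRUE,
                          correct_basis_purity = TRUE,
                          asymptotes = c("fixed", "free"),
                          drop_basis_points = FALSE) {
  asymptotes <- match.arg(asymptotes)
  series <- lapply(series, function(el) {
    if (inherits(el, "pes_spectrum")) {
      list(pH = el$meta$pH, spectrum = el)
    } else {
      list(pH = as.numeric(el$pH), spectrum = el$spectrum)
    }
  })
  ph <- vapply(series, `[[`, numeric(1), "pH")
  if (any(!is.finite(ph))) {
    stop("every spectrum in the series needs a finite pH", call. = FALSE)
  }
  ord <- order(ph)
  series <- series[ord]
  ph <- ph[ord]

  calibrated <- FALSE
  if (!is.null(references) && !is.null(reference_center)) {
    if (length(references) != length(series)) {
      stop("`references` must be parallel to `series`", call. = FALSE)
    }
    references <- references[ord]
    for (i in seq_along(series)) {
      cal <- calibrate_to_reference(
        references[[i]], reference_center,
        search_window = reference_center + c(-4, 4))
      series[[i]]$spectrum <- shift_energy(series[[i]]$spectrum,
                                           -cal$detected_offset)
    }
    calibrated <- TRUE
    align <- FALSE
  }

  pick_member <- function(x, default_idx, what) {
    if (is.null(x)) return(default_idx)
    if (is.numeric(x) && length(x) == 1L) {
      idx <- which(abs(ph - x) < 1e-9)
      if (!length(idx)) {
        stop("no spectrum in the series at ", what, " = ", x,
             call. = FALSE)
      }
      return(idx[1L])
    }
    NA_integer_
  }
  i_low <- pick_member(basis_low, 1L, "basis_low")
  i_high <- pick_member(basis_high, length(series), "basis_high")
  from_series <- c(low = !is.na(i_low), high = !is.na(i_high))
  if (!is.na(i_low)) basis_low <- series[[i_low]]$spectrum
  if (!is.na(i_high)) basis_high <- series[[i_high]]$spectrum

  bases_from_series <- all(from_series)
  free_asym <- asymptotes == "free"

  keep <- rep(TRUE, length(series))
  if (drop_basis_points || free_asym ||
      (bases_from_series && correct_basis_purity)) {
    if (from_series[["low"]]) keep[i_low] <- FALSE
    if (from_series[["high"]]) keep[i_high] <- FALSE
  }

  basis_ph <- NULL
  if (isTRUE(correct_basis_purity)) {
    bp <- c(basis_low$meta$pH, basis_high$meta$pH)
    if (all(is.finite(bp)) && abs(diff(bp)) > 1e-9) basis_ph <- bp
  }

  # Default analysis window: the support of the basis curves. The flanks
  # of the spectrum carry no composition signal but still contribute
  # counting noise to normalization and moment estimates.
  if (is.null(window)) {
    window <- signal_window(basis_low, basis_high)
  }

  # The basis curves' relative alignment matters for every unmixing, but a
  # single-peak center fit on one noisy spectrum estimates it poorly.
  # After coarse peak alignment the relative offset is refined once per
  # series with an estimator that is linear in the unmixing residuals.
  # (With external calibration the residual offsets are already below
  # what this refinement can resolve, so it is skipped.)
  align_bases_once <- align && length(series) >= 3L
  if (align_bases_once) {
    ca <- main_peak_center(basis_low, align_window)
    cb <- main_peak_center(basis_high, align_window)
    bh0 <- shift_energy(basis_high, ca - cb)
    # The basis spectra themselves match their own curve at any offset,
    # so only the remaining members inform the residual offset. The
    # offset estimate is linear in the unmixing residuals (first-order
    # expansion in the shift), hence unbiased under noise, unlike a
    # profiled residual minimization.
    informative <- seq_along(series)
    if (from_series[["low"]]) informative <- setdiff(informative, i_low)
    if (from_series[["high"]]) informative <- setdiff(informative, i_high)
    if (length(informative)) {
      num <- 0
      den_db <- 0
      for (el in series[informative]) {
        u <- fit_two_basis(el$spectrum, basis_low, bh0, align = align,
                           window = window, align_window = align_window,
                           align_basis_b = FALSE)
        wgt <- 1 - min(1, max(0, u$ratio_raw))
        num <- num + wgt * u$b_grad_moment
        den_db <- den_db + wgt^2 * u$b_grad_norm2
      }
      if (den_db > 0) {
        db <- -num / den_db
        basis_high <- shift_energy(bh0, min(0.05, max(-0.05, db)))
      } else {
        basis_high <- bh0
      }
    } else {
      basis_high <- bh0
    }
  }

  unmix_and_fit <- function(bl, bh) {
    per_target_bases <- is.list(bl) && !inherits(bl, "pes_spectrum")
    unmix <- vector("list", length(series))
    for (i in seq_along(series)) {
      unmix[[i]] <- fit_two_basis(
        series[[i]]$spectrum,
        if (per_target_bases) bl[[i]] else bl,
        if (per_target_bases) bh[[i]] else bh,
        align = align, window = window, align_window = align_window,
        align_basis_b = !align_bases_once)
    }
    proj <- t(vapply(unmix, `[[`, numeric(3), "noise_projections"))
    pts <- data.frame(
      pH = ph,
      ratio = vapply(unmix, `[[`, numeric(1), "ratio"),
      ratio_raw = vapply(unmix, `[[`, numeric(1), "ratio_raw"),
      ratio_uncertainty = vapply(unmix, `[[`, numeric(1),
                                 "ratio_uncertainty"),
      target_noise_sd = proj[, "target"])

    # Basis noise adds curve-wide correlated error only when the bases are
    # measured spectra with appreciable noise; its 1-sigma projections
    # feed the GLS covariance in fit_pka. Unclipped ratios avoid
    # censoring bias.
    basis_noise_sd <- c(stats::median(proj[, "basis_a"]),
                        stats::median(proj[, "basis_b"]))
    use_gls <- !free_asym && !is.null(basis_ph) &&
      any(basis_noise_sd > 1e-8)

    res <- fit_pka(pts$pH[keep], pts$ratio_raw[keep],
                   ratio_uncertainty = pmax(pts$target_noise_sd[keep], 1e-8),
                   basis_ph = basis_ph, free_asymptotes = free_asym,
                   basis_noise_sd = if (use_gls) basis_noise_sd else NULL)
    res$unmixing <- unmix
    res$all_points <- pts
    res
  }

  unmix_and_fit(basis_low, basis_high)
}

# Support of the basis envelopes: the energy range where the (lightly
# smoothed) larger of the two basis curves exceeds `frac` of its maximum,
# padded by `pad` eV on both sides and clipped to the common grid span.
signal_window <- function(basis_low, basis_high, frac = 0.005, pad = 0.5) {
  lo <- max(min(basis_low$energy), min(basis_high$energy))
  hi <- min(max(basis_low$energy), max(basis_high$energy))
  grid <- basis_low$energy[basis_low$energy >= lo & basis_low$energy <= hi]
  if (length(grid) < 10L) return(c(lo, hi))
  ya <- interpolate_spectrum(basis_low, grid)$intensity
  yb <- interpolate_spectrum(basis_high, grid)$intensity
  y <- boxcar_smooth(pmax(ya / max(ya), yb / max(yb)), 11L)
  above <- which(y > frac * max(y))
  if (!length(above)) return(c(lo, hi))
  c(max(lo, grid[min(above)] - pad), min(hi, grid[max(above)] + pad))
}
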