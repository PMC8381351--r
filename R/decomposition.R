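#' Constrained cumulative Gaussian fit of a spectrum
#'
#' Fits a sum of Gaussian components to a spectrum inside `fit_window` by
#' bounded Levenberg-Marquardt least squares. Constraints declared on the
#' [peak_model()] — fixed centers and area ratios — are enforced exactly by
#' reparameterization: constrained quantities are eliminated from the
#' parameter vector and reconstructed from their masters, so they hold at
#' every optimizer step.
#'
#' Bounds follow physical plausibility: widths in [0.05, 2] eV, centers
#' inside the fit window, areas non-negative. Parameter uncertainties come
#' from the covariance of the converged fit; for constrained quantities the
#' master's uncertainty is propagated (fixed centers have uncertainty 0).
#'
#' @param spectrum A [pes_spectrum()] covering `fit_window`.
#' @param model A [peak_model()] whose component values serve as starting
#'   values (centers must lie inside the window).
#' @param fit_window Length-2 numeric window (eV).
#' @param sigma_bounds Length-2 bounds on component widths (eV).
#' @param max_iter Iteration cap for the optimizer.
#' @return A `pes_fit` object: list with `components` (fitted
#'   [gaussian_component()]s), `center_uncertainties`, `sigma_uncertainties`,
#'   `area_uncertainties`, `residual_rms`, `converged` and `message`.
#' @examples
#' sp <- simulate_spectrum_from_vies(c(292.9, rep(291.5, 5)), 0.45)
#' m <- peak_model(
#'   list(gaussian_component(293.1, 0.5, 1), gaussian_component(291.3, 0.5, 5)),
#'   constraints = list(area_ratio(1, 2, 1 / 5)))
#' fit_peak_model(sp, m, fit_window = c(288, 296))
#' @export
fit_peak_model <- function(spectrum, model, fit_window,
                           sigma_bounds = c(0.05, 2.0), max_iter = 500) {
  stopifnot(inherits(model, "peak_model"))
  fit_window <- sort(as.numeric(fit_window))
  keep <- spectrum$energy >= fit_window[1] & spectrum$energy <= fit_window[2]
  if (sum(keep) < 5L) {
    stop("spectrum does not cover the fit window", call. = FALSE)
  }
  x <- spectrum$energy[keep]
  y <- spectrum$intensity[keep]

  map <- build_parameter_map(model, fit_window, sigma_bounds)
  if (length(map$start) == 0L) {
    stop("peak model has no free parameters", call. = FALSE)
  }
  if (any(map$center_fixed_value < fit_window[1] - 1e-9 |
          map$center_fixed_value > fit_window[2] + 1e-9, na.rm = TRUE)) {
    stop("a fixed center lies outside the fit window", call. = FALSE)
  }

  model_fn <- function(pars) {
    cmp <- expand_parameters(pars, map)
    out <- rep(0, length(x))
    for (k in seq_len(nrow(cmp))) {
      z <- (x - cmp$center[k]) / cmp$sigma[k]
      out <- out + cmp$area[k] * exp(-0.5 * z * z) /
        (cmp$sigma[k] * sqrt(2 * pi))
    }
    out
  }
  fit <- minpack.lm::nls.lm(
    par = map$start, lower = map$lower, upper = map$upper,
    fn = function(p) model_fn(p) - y,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))

  converged <- fit$info %in% 1:4
  cmp <- expand_parameters(fit$par, map)
  rss <- sum(fit$fvec^2)
  dof <- max(1L, length(y) - length(fit$par))
  s2 <- rss / dof

  se <- rep(NA_real_, length(fit$par))
  hv <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(hv, "try-error")) {
    dg <- diag(hv)
    dg[dg < 0] <- NA_real_
    se <- sqrt(2 * s2 * dg)  # hessian of SSR = 2 J'J at the optimum
  }
  unc <- propagate_uncertainties(se, map)

  components <- lapply(seq_len(nrow(cmp)), function(k) {
    gaussian_component(cmp$center[k], cmp$sigma[k], cmp$area[k])
  })
  structure(
    list(components = components,
         center_uncertainties = unc$center,
         sigma_uncertainties = unc$sigma,
         area_uncertainties = unc$area,
         residual_rms = sqrt(rss / length(y)),
         converged = converged,
         message = fit$message,
         fit_window = fit_window),
    class = "pes_fit")
}

#' @export
print.pes_fit <- function(x, ...) {
  cat(sprintf("<pes_fit> %d components, residual RMS %.4g, %s\n",
              length(x$components), x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  for (k in seq_along(x$components)) {
    cc <- x$components[[k]]
    cat(sprintf("  [%d] center %.3f +/- %.3f eV  sigma %.3f eV  area %.4g\n",
                k, cc$center, x$center_uncertainties[k], cc$sigma, cc$area))
  }
  invisible(x)
}

# Builds the free-parameter vector for a constrained peak model.
# Free parameters: one sigma (shared) or one per component; centers without
# a fixed_center constraint; areas of components that are not the `a` side
# of an area_ratio constraint. Area-ratio chains (a tied to b tied to c) are
# resolved recursively.
build_parameter_map <- function(model, fit_window, sigma_bounds) {
  n <- length(model$components)
  center0 <- vapply(model$components, `[[`, numeric(1), "center")
  sigma0 <- vapply(model$components, `[[`, numeric(1), "sigma")
  area0 <- vapply(model$components, `[[`, numeric(1), "area")

  center_fixed <- rep(FALSE, n)
  center_fixed_value <- rep(NA_real_, n)
  area_master <- seq_len(n)   # component whose area parameter feeds this one
  area_factor <- rep(1, n)

  for (con in model$constraints) {
    if (con$type == "fixed_center") {
      center_fixed[con$component] <- TRUE
      center_fixed_value[con$component] <- con$value
    } else if (con$type == "area_ratio") {
      area_master[con$a] <- con$b
      area_factor[con$a] <- con$ratio
    }
  }
  # resolve chains to a root master
  for (i in seq_len(n)) {
    seen <- i
    while (area_master[seen[length(seen)]] != seen[length(seen)]) {
      nxt <- area_master[seen[length(seen)]]
      if (nxt %in% seen) stop("circular area-ratio constraints", call. = FALSE)
      seen <- c(seen, nxt)
    }
    root <- seen[length(seen)]
    f <- 1
    j <- i
    while (j != root) {
      f <- f * area_factor[j]
      j <- area_master[j]
    }
    area_master[i] <- root
    area_factor[i] <- f
  }

  start <- numeric()
  lower <- numeric()
  upper <- numeric()
  nm <- character()

  if (model$share_sigma) {
    start <- c(start, mean(sigma0)); nm <- c(nm, "sigma")
    lower <- c(lower, sigma_bounds[1]); upper <- c(upper, sigma_bounds[2])
  } else {
    for (i in seq_len(n)) {
      start <- c(start, sigma0[i]); nm <- c(nm, paste0("sigma", i))
      lower <- c(lower, sigma_bounds[1]); upper <- c(upper, sigma_bounds[2])
    }
  }
  for (i in seq_len(n)) {
    if (!center_fixed[i]) {
      start <- c(start, center0[i]); nm <- c(nm, paste0("center", i))
      lower <- c(lower, fit_window[1]); upper <- c(upper, fit_window[2])
    }
  }
  for (i in seq_len(n)) {
    if (area_master[i] == i) {
      start <- c(start, area0[i]); nm <- c(nm, paste0("area", i))
      lower <- c(lower, 0); upper <- c(upper, Inf)
    }
  }
  names(start) <- nm
  list(start = start, lower = lower, upper = upper, n = n,
       share_sigma = model$share_sigma,
       center_fixed = center_fixed, center_fixed_value = center_fixed_value,
       area_master = area_master, area_factor = area_factor)
}

expand_parameters <- function(pars, map) {
  n <- map$n
  sigma <- if (map$share_sigma) rep(pars[["sigma"]], n) else
    vapply(seq_len(n), function(i) pars[[paste0("sigma", i)]], numeric(1))
  center <- numeric(n)
  for (i in seq_len(n)) {
    center[i] <- if (map$center_fixed[i]) map$center_fixed_value[i] else
      pars[[paste0("center", i)]]
  }
  area <- numeric(n)
  for (i in seq_len(n)) {
    area[i] <- map$area_factor[i] * pars[[paste0("area", map$area_master[i])]]
  }
  data.frame(center = center, sigma = sigma, area = area)
}

propagate_uncertainties <- function(se, map) {
  n <- map$n
  names(se) <- names(map$start)
  s_sigma <- if (map$share_sigma) rep(se[["sigma"]], n) else
    vapply(seq_len(n), function(i) se[[paste0("sigma", i)]], numeric(1))
  s_center <- vapply(seq_len(n), function(i) {
    if (map$center_fixed[i]) 0 else se[[paste0("center", i)]]
  }, numeric(1))
  s_area <- vapply(seq_len(n), function(i) {
    map$area_factor[i] * se[[paste0("area", map$area_master[i])]]
  }, numeric(1))
  list(center = s_center, sigma = s_sigma, area = s_area)
}

#' Two-basis linear unmixing of a mixed-species spectrum
#'
#' Models the target as `ratio * basis_a + (1 - ratio) * basis_b` — the
#' photoemission-titration relation with the pure low-pH (protonated) and
#' high-pH (deprotonated) spectra as basis curves — and estimates `ratio`
#' by least squares, bounded to [0, 1]. All three spectra are area-normalized
#' over a common window and interpolated to the target grid first; with
#' `align = TRUE` the target is pre-shifted so its main feature overlaps the
#' basis features (removing residual charging offsets).
#'
#' The mixture is estimated scale-invariantly: the target is regressed on
#' both bases with free coefficients, `t ~ alpha*A + beta*B`, and the
#' ratio is `alpha / (alpha + beta)`. This is the same two-state model —
#' for area-normalized spectra `alpha + beta = 1` up to noise — but it
#' cancels the error that counting noise induces in each spectrum's
#' normalization integral, which would otherwise couple into the ratio.
#' Because the basis curves are measured spectra with the same counting
#' noise as the target, the Gram matrix of the regression is additionally
#' debiased by the expected noise contribution to `||A||^2` and `||B||^2`
#' (noise inflation there shrinks every ratio toward 0.5, flattening a
#' titration curve built from such ratios), with each spectrum's noise
#' variance estimated robustly from its second differences. For noiseless
#' input both corrections are vanishingly small and exact mixtures are
#' recovered to machine precision.
#'
#' @param target,basis_a,basis_b [pes_spectrum()] objects.
#' @param align Logical; overlap the main feature of the target *and* of
#'   `basis_b` with that of `basis_a` before fitting (all three spectra may
#'   carry independent charging offsets). Coarse alignment locates each
#'   spectrum's main peak with a single-Gaussian fit; the target's shift is
#'   then refined jointly with the mixing ratio against the full two-basis
#'   model, which removes the composition-dependent pull that the shoulder
#'   exerts on a single-peak center estimate.
#' @param window Normalization/fit window (eV); default spans the
#'   intersection of all three grids.
#' @param align_window Half-width in eV of the per-spectrum window around
#'   each spectrum's intensity maximum used to locate the main feature
#'   (default 1.0), or a length-2 absolute window applied to all spectra.
#' @param smooth_ev Width (eV) of a boxcar smoothing kernel applied
#'   identically to the target and both bases before fitting (default 0.1,
#'   well below the spectral widths; 0 disables). Because the kernel is
#'   linear and shared, exact mixtures remain exact while the common-mode
#'   basis noise that distorts a whole titration curve is suppressed.
#' @param refine_shift Refine the target's alignment jointly with the
#'   mixing ratio (see `align`); default `TRUE`.
#' @param align_basis_b Align `basis_b`'s main peak to `basis_a`'s
#'   (default `TRUE`). Set `FALSE` when the caller has already aligned the
#'   bases, e.g. with a series-level estimate of their relative offset.
#' @return An `unmix_result`: list with `ratio` (bounded to [0, 1]),
#'   `ratio_uncertainty`, `ratio_raw` (the unbounded estimate — prefer it
#'   when feeding ratios into a downstream fit, since clipping censors the
#'   noise distribution near the endpoints), `residual_rms`, `at_bound`
#'   (TRUE if the estimate was clipped), `applied_shift` (eV, shift applied
#'   to the target) and `noise_projections` (1-sigma contributions of the
#'   target's and each basis's noise to the ratio).
#' @export
fit_two_basis <- function(target, basis_a, basis_b, align = TRUE,
                          window = NULL, align_window = 1.0,
                          smooth_ev = 0.1, refine_shift = TRUE,
                          align_basis_b = TRUE) {
  applied_shift <- 0
  if (align) {
    ca <- main_peak_center(basis_a, align_window)
    ct <- main_peak_center(target, align_window)
    applied_shift <- ca - ct
    target <- shift_energy(target, applied_shift)
    if (align_basis_b) {
      cb <- main_peak_center(basis_b, align_window)
      basis_b <- shift_energy(basis_b, ca - cb)
    }
  }
  if (is.null(window)) {
    window <- c(max(min(target$energy), min(basis_a$energy),
                    min(basis_b$energy)),
                min(max(target$energy), max(basis_a$energy),
                    max(basis_b$energy)))
  }
  window <- sort(as.numeric(window))

  grid <- target$energy[target$energy >= window[1] &
                          target$energy <= window[2]]
  if (length(grid) < 5L) {
    stop("common window contains too few grid points", call. = FALSE)
  }
  # Each spectrum is interpolated to the common grid and area-normalized.
  # Noise variances are estimated on each spectrum's OWN grid (where the
  # noise is uncorrelated and the second-difference estimator is unbiased)
  # and then scaled: linear interpolation at fractional position w
  # multiplies the marginal noise variance by (1-w)^2 + w^2, and a
  # width-k boxcar by a further 1/k. Projections onto smooth directions
  # keep the raw (pre-interpolation) variance, because the adjoint of
  # both operations leaves a smooth vector essentially unchanged.
  prep <- function(sp) {
    yi <- interpolate_spectrum(sp, grid)
    area <- spectrum_integral(yi)
    if (!is.finite(area) || area <= 0) {
      stop("cannot area-normalize: integral over window is not positive",
           call. = FALSE)
    }
    keep_src <- sp$energy >= window[1] & sp$energy <= window[2]
    v_src <- if (sum(keep_src) >= 4L) {
      noise_variance(sp$intensity[keep_src]) / area^2
    } else 0
    list(y = yi$intensity / area, v_src = v_src,
         v_marg = v_src * interp_var_factor(sp$energy, grid))
  }
  pt <- prep(target)
  pa <- prep(basis_a)
  pb <- prep(basis_b)
  t_n <- pes_spectrum(grid, pt$y, pH = target$meta$pH,
                      region = target$meta$region,
                      resolution_fwhm = target$meta$resolution_fwhm,
                      label = target$meta$label)
  a_n <- t_n; a_n$intensity <- pa$y
  b_n <- t_n; b_n$intensity <- pb$y

  if (smooth_ev > 0) {
    k_pts <- max(1L, as.integer(round(smooth_ev / stats::median(diff(grid)))))
    if (k_pts %% 2L == 0L) k_pts <- k_pts + 1L
    t_n$intensity <- boxcar_smooth(t_n$intensity, k_pts)
    a_n$intensity <- boxcar_smooth(a_n$intensity, k_pts)
    b_n$intensity <- boxcar_smooth(b_n$intensity, k_pts)
    # a width-k boxcar re-absorbs the neighbor correlation created by
    # interpolation: m + 2w(1-w) = 1, so the smoothed marginal variance
    # is v_src / k independent of the interpolation offset
    va <- pa$v_src / k_pts
    vb <- pb$v_src / k_pts
  } else {
    va <- pa$v_marg
    vb <- pb$v_marg
  }

  ya <- a_n$intensity
  yb <- b_n$intensity
  d <- ya - yb
  ss_d <- sum(d^2)
  if (ss_d <= 1e-20 * sum(ya^2)) {
    stop("basis spectra are identical: mixing ratio is unidentifiable",
         call. = FALSE)
  }
  n_pts <- length(grid)
  # Gram matrix debiasing for noisy basis curves: with A = A0 + eA,
  # E||A||^2 = ||A0||^2 + n*var(eA) (analogously for B), while the cross
  # moment <A, B> is unbiased.
  G <- matrix(c(sum(ya^2) - n_pts * va, sum(ya * yb),
                sum(ya * yb), sum(yb^2) - n_pts * vb), 2L, 2L)
  if (G[1, 1] <= 0 || G[2, 2] <= 0 ||
      (det_g <- G[1, 1] * G[2, 2] - G[1, 2]^2) <= 0) {
    stop("basis spectra differ by less than their noise: mixing ratio is ",
         "unidentifiable", call. = FALSE)
  }
  den <- ss_d - n_pts * (va + vb)
  if (den <= 0) {
    stop("basis spectra differ by less than their noise: mixing ratio is ",
         "unidentifiable", call. = FALSE)
  }
  # Matched scale functional: w lies in span{A, B} with <A,w> = <B,w> = 1,
  # so <t, w> estimates the target's scale in the basis frame for ANY
  # mixture, with far less noise than an area integral (it weights by
  # signal instead of weighting all grid points equally).
  w_scale <- cbind(ya, yb) %*% solve(G, c(1, 1))
  solve_ratio <- function(ty) {
    s <- sum(ty * w_scale)
    if (!is.finite(s) || abs(s) < 1e-12) {
      stop("degenerate mixture fit: target has no overlap with the bases",
           call. = FALSE)
    }
    ty_s <- ty / s
    r <- (sum((ty_s - yb) * d) - n_pts * vb) / den
    list(ratio = r, scale = s, ty_s = ty_s)
  }
  est <- solve_ratio(t_n$intensity)

  if (align && refine_shift) {
    # Joint refinement of the target shift against the fitted mixture:
    # a single-peak center estimate is pulled by the shoulder in a
    # composition-dependent way; minimizing the mixture residual over a
    # residual shift removes that systematic and its noise jitter.
    ty0 <- t_n$intensity
    dd <- 0
    for (it in 1:2) {
      r_cl <- min(1, max(0, est$ratio))
      model_y <- r_cl * ya + (1 - r_cl) * yb
      obj <- function(s) {
        ts <- stats::approx(grid + s, ty0, xout = grid, rule = 2)$y
        sc <- sum(ts * w_scale)
        if (abs(sc) < 1e-12) return(Inf)
        sum((ts / sc - model_y)^2)
      }
      dd <- stats::optimize(obj, c(-0.08, 0.08), tol = 1e-6)$minimum
      est <- solve_ratio(stats::approx(grid + dd, ty0, xout = grid,
                                       rule = 2)$y)
    }
    t_n$intensity <- stats::approx(grid + dd, ty0, xout = grid, rule = 2)$y
    applied_shift <- applied_shift + dd
  }

  r_hat <- est$ratio
  at_bound <- r_hat < 0 || r_hat > 1
  r <- min(1, max(0, r_hat))

  resid <- est$ty_s - (r * ya + (1 - r) * yb)
  dof <- max(1L, length(grid) - 2L)
  s2 <- sum(resid^2) / dof
  # moments against the energy gradient of basis_b, used by callers that
  # estimate a residual relative offset of the bases across a whole series
  dx <- stats::median(diff(grid))
  b_grad <- c(0, diff(yb, lag = 2L) / (2 * dx), 0)
  b_grad_moment <- sum(resid * b_grad)
  b_grad_norm2 <- sum(b_grad^2)
  # target-noise propagation: white component along the basis difference
  # plus the (small) noise of the matched scale estimate, which couples
  # into the ratio through the overlap of the target with that direction
  vt <- pt$v_src / est$scale^2
  kappa <- sum(est$ty_s * d) / den
  var_scale_rel <- drop(t(c(1, 1)) %*% solve(G, c(1, 1)))
  var_target <- vt * (1 / den + var_scale_rel * kappa^2)
  structure(
    list(ratio = r, ratio_uncertainty = sqrt(max(s2 / den, 0)),
         ratio_raw = r_hat,
         scale = est$scale,
         residual_rms = sqrt(mean(resid^2)),
         at_bound = at_bound, applied_shift = applied_shift,
         b_grad_moment = b_grad_moment, b_grad_norm2 = b_grad_norm2,
         # 1-sigma projections of each spectrum's noise onto the unmixing
         # estimate: the error budget of `ratio` (target: independent
         # part; bases: curve-wide common modes)
         noise_projections = c(
           target = sqrt(max(var_target, 0)),
           basis_a = sqrt(pa$v_src / ss_d),
           basis_b = sqrt(pb$v_src / ss_d))),
    class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf("<unmix_result> ratio %.4f +/- %.4f (residual RMS %.3g)%s\n",
              x$ratio, x$ratio_uncertainty, x$residual_rms,
              if (x$at_bound) " [pinned at bound]" else ""))
  invisible(x)
}

# Running mean with edge replication; width forced odd. Purely linear, so
# it commutes with mixing and scaling.
boxcar_smooth <- function(y, width) {
  width <- as.integer(width)
  if (width <= 1L) return(y)
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(y)
  pad <- (width - 1L) %/% 2L
  yp <- c(rep(y[1L], pad), y, rep(y[n], pad))
  out <- stats::filter(yp, rep(1 / width, width), sides = 2L)
  as.numeric(out)[(pad + 1L):(pad + n)]
}

# Mean variance-scaling factor of linear interpolation from `src` grid
# positions onto `xout`: sampling between nodes at fractional position w
# gives white noise a marginal variance factor (1-w)^2 + w^2.
interp_var_factor <- function(src, xout) {
  idx <- findInterval(xout, src)
  idx <- pmin(pmax(idx, 1L), length(src) - 1L)
  w <- (xout - src[idx]) / (src[idx + 1L] - src[idx])
  w <- pmin(pmax(w, 0), 1)
  mean((1 - w)^2 + w^2)
}

# Robust per-spectrum noise-variance estimate from second differences:
# for iid noise Var(diff(y, 2)) = 6*sigma^2, while a smooth spectral
# envelope contributes only curvature * dx^2, negligible on a dense grid.
# mad() keeps the few high-curvature points near peaks from inflating it.
noise_variance <- function(y) {
  if (length(y) < 4L) return(0)
  (stats::mad(diff(y, differences = 2L)) / sqrt(6))^2
}

# Locates a spectrum's main feature by a single-Gaussian fit, either in a
# window of +/- `align_window` eV around the intensity maximum (scalar) or
# in an absolute length-2 window.
main_peak_center <- function(spectrum, align_window = 1.0) {
  if (length(align_window) == 2L) {
    window <- sort(as.numeric(align_window))
  } else {
    cmax <- spectrum$energy[which.max(spectrum$intensity)]
    window <- cmax + c(-1, 1) * align_window
  }
  keep <- spectrum$energy >= window[1] & spectrum$energy <= window[2]
  if (sum(keep) < 5L) stop("alignment window too narrow", call. = FALSE)
  fit_single_gaussian(spectrum$energy[keep], spectrum$intensity[keep])$center
}
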