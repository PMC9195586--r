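#' Phase estimate container
#'
#' Result of one characterization method applied to one spectrum.  The
#' centroid methods (A-D) return a raw statistic (nm for A, dimensionless
#' normalized-detuning units for B-D) and acquire a calibrated phase only
#' through [build_calibration()]; the transition-equation, classical and
#' maximum-likelihood methods return the phase directly.
#'
#' @param method Method identifier, one of `"A"`, `"B"`, `"C"`, `"D"`,
#'   `"E"`, `"classical"`, `"ml"`.
#' @param statistic Raw characterization value.
#' @param delta_hat Calibrated phase (rad) or `NA` for uncalibrated
#'   centroid statistics.
#' @param diagnostics Named list of method diagnostics (convergence flags,
#'   residuals, root sets, ...).
#' @return An object of class `"phase_estimate"`.
#' @export
phase_estimate <- function(method, statistic, delta_hat = NA_real_,
                           diagnostics = list()) {
  if (!is.na(delta_hat) && !is.finite(delta_hat))
    stop("delta_hat must be finite when present", call. = FALSE)
  structure(list(method = method, statistic = statistic,
                 delta_hat = delta_hat, diagnostics = diagnostics),
            class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat(sprintf("Phase estimate [method %s]: statistic = %.8g", x$method,
              x$statistic))
  if (!is.na(x$delta_hat)) cat(sprintf(", delta_hat = %.8g rad", x$delta_hat))
  cat("\n")
  invisible(x)
}

#' Normalize a readout spectrum
#'
#' Converts a spectrum to the dimensionless form the estimating equations
#' operate on: detunings `u = (lambda - lambda0) / sigma_lambda` and
#' intensities scaled so the fitted envelope amplitude is 1.
#'
#' The amplitude is obtained from the spectrum itself by linear least
#' squares against the interference basis
#' `{phi, phi cos(kx), phi sin(kx)}`, where `phi` is the source envelope
#' (Gaussian by default, or the measured `source` profile).  For model
#' spectra `A (1 - rho cos(kx + delta)) phi` the first coefficient is
#' exactly `A`.  Fitting the amplitude per spectrum makes every
#' phase-from-intensity estimator invariant to overall intensity rescaling;
#' at very weak coupling the basis becomes nearly collinear and the
#' amplitude (hence the phase read from intensity ratios) degrades
#' gracefully with noise — the expected behaviour of a classical intensity
#' readout without a reference channel.
#'
#' @param spec A [spectrum()].
#' @param config An [optical_config()].
#' @param source Optional source [spectrum()] on the same grid; its profile
#'   (scaled to maximum 1) replaces the Gaussian envelope weights.
#' @return An object of class `"normalized_spectrum"` with fields `u`
#'   (detunings), `y` (normalized intensities), `w` (source-envelope
#'   weights in `[0, 1]`), `x` (detunings in nm), `amplitude` (the fitted
#'   envelope amplitude), and `delta_init` (a crude phase guess from the
#'   fit, useful for bracketing).
#' @export
normalize_spectrum <- function(spec, config, source = NULL) {
  stopifnot(inherits(spec, "spectrum"), inherits(config, "optical_config"))
  if (sum(spec$intensities) <= 0)
    stop("cannot normalize a spectrum with zero total intensity",
         call. = FALSE)
  x <- spec$wavelengths - config$lambda0
  u <- x / config$sigma_lambda
  if (is.null(source)) {
    w <- exp(-u^2)
  } else {
    stopifnot(inherits(source, "spectrum"))
    if (length(source$wavelengths) != length(spec$wavelengths) ||
        any(abs(source$wavelengths - spec$wavelengths) >
            1e-9 * config$lambda0))
      stop("source spectrum must share the grid of `spec`", call. = FALSE)
    m <- max(source$intensities)
    if (m <= 0) stop("source spectrum has zero intensity", call. = FALSE)
    w <- source$intensities / m
  }
  basis <- cbind(w, w * cos(config$k * x), w * sin(config$k * x))
  fit <- stats::lm.fit(basis, spec$intensities)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  amplitude <- cf[[1]]
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("could not determine a positive envelope amplitude", call. = FALSE)
  structure(
    list(u = u, x = x, y = spec$intensities / amplitude, w = w,
         amplitude = amplitude,
         delta_init = atan2(cf[[3]], -cf[[2]]),
         lambda0 = config$lambda0, sigma_lambda = config$sigma_lambda),
    class = "normalized_spectrum")
}

.check_nspec <- function(nspec) {
  stopifnot(inherits(nspec, "normalized_spectrum"))
}

#' Construct a normalized spectrum directly
#'
#' Builds the dimensionless container used by the phase estimators from
#' already-normalized data, bypassing the amplitude fit of
#' [normalize_spectrum()].  Useful for feeding analytic or external data
#' to [classical_estimate()], [ml_estimate()] and [method_e()].
#'
#' @param u Normalized detunings `(lambda - lambda0) / sigma_lambda`.
#' @param y Normalized intensities (envelope amplitude approximately 1).
#' @param w Source-envelope weights in `[0, 1]`; Gaussian by default.
#' @param sigma_lambda Envelope scale (nm) used to map `u` back to nm.
#' @param lambda0 Center wavelength (nm).
#' @return An object of class `"normalized_spectrum"`.
#' @export
normalized_spectrum <- function(u, y, w = exp(-u^2), sigma_lambda = 1,
                                lambda0 = 0) {
  u <- as.numeric(u); y <- as.numeric(y); w <- as.numeric(w)
  if (length(u) != length(y) || length(u) != length(w))
    stop("u, y and w must have equal length", call. = FALSE)
  if (any(y < 0)) stop("normalized intensities must be non-negative",
                       call. = FALSE)
  if (any(w < 0) || any(w > 1)) stop("weights must lie in [0, 1]",
                                     call. = FALSE)
  structure(list(u = u, x = u * sigma_lambda, y = y, w = w,
                 amplitude = 1, delta_init = NA_real_,
                 lambda0 = lambda0, sigma_lambda = sigma_lambda),
            class = "normalized_spectrum")
}

#' Method A: unweighted spectral centroid
#'
#' The raw intensity centroid of the spectrum relative to a reference
#' wavelength (nm).  In the weak-value regime the centroid shift is
#' proportional to the imaginary part of the weak value and hence, near the
#' working point, to the phase; the proportionality constant is acquired by
#' calibration, not returned here.
#'
#' @param spec A [spectrum()].
#' @param config An [optical_config()].
#' @param reference_centroid Reference wavelength subtracted from the
#'   centroid (nm); defaults to the source center.
#' @return A [phase_estimate()] with the centroid shift (nm) as statistic
#'   and no calibrated phase.
#' @export
method_a <- function(spec, config, reference_centroid = config$lambda0) {
  stopifnot(inherits(spec, "spectrum"))
  tot <- sum(spec$intensities)
  if (tot <= 0) stop("zero total intensity", call. = FALSE)
  stat <- sum(spec$wavelengths * spec$intensities) / tot - reference_centroid
  phase_estimate("A", stat, diagnostics = list(converged = TRUE))
}

# shared weighted-centroid kernel: sum(w u y) / sum(w y), u from config
.weighted_centroid <- function(spec, config, w) {
  u <- (spec$wavelengths - config$lambda0) / config$sigma_lambda
  den <- sum(w * spec$intensities)
  if (den <= 0) stop("zero weighted intensity mass", call. = FALSE)
  sum(w * u * spec$intensities) / den
}

#' Method B: Gaussian-weighted spectral centroid
#'
#' Weighted centroid in normalized detuning units with the nominal source
#' Gaussian as weight, `w = exp(-u^2)`.  This is the weak-limit
#' characterization: for small phases `tan(delta)` is `k sigma_lambda`
#' times this statistic.
#'
#' @inheritParams method_a
#' @return A [phase_estimate()] with the weighted centroid (dimensionless)
#'   as statistic.
#' @export
method_b <- function(spec, config) {
  stopifnot(inherits(spec, "spectrum"), inherits(config, "optical_config"))
  u <- (spec$wavelengths - config$lambda0) / config$sigma_lambda
  stat <- .weighted_centroid(spec, config, exp(-u^2))
  phase_estimate("B", stat, diagnostics = list(converged = TRUE))
}

#' Fit a skew-Gaussian profile to a source spectrum
#'
#' Models the source as a piecewise Gaussian with separate scales left and
#' right of the center,
#' `I = A exp(-(lambda - c)^2 / sigma1^2)` for `lambda < c` and
#' `sigma2` for `lambda > c`.  The center and amplitude come from a
#' log-domain parabola through the three points around the maximum (exact
#' for Gaussian data); each side scale is then found by damped Newton
#' iteration on the stationarity condition of the least-squares objective
#' in intensity space (step halving when the residual increases).
#'
#' @param source A unimodal source [spectrum()].
#' @param tol Convergence tolerance on the Newton step (nm).
#' @param max_iter Maximum Newton iterations per side.
#' @return An object of class `"skew_gaussian_fit"` with fields `center`,
#'   `sigma_left`, `sigma_right`, `amplitude`, `converged`, `iterations`.
#'   Non-convergence and underdetermined inputs are flagged, not raised.
#' @export
fit_skew_gaussian <- function(source, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(source, "spectrum"))
  wl <- source$wavelengths; it <- source$intensities
  bad <- function(reason) structure(
    list(center = NA_real_, sigma_left = NA_real_, sigma_right = NA_real_,
         amplitude = NA_real_, converged = FALSE, iterations = 0L,
         reason = reason),
    class = "skew_gaussian_fit")
  i0 <- which.max(it)
  if (i0 <= 1L || i0 >= length(it) || it[i0] <= 0)
    return(bad("peak on grid boundary or empty spectrum"))
  tri <- it[(i0 - 1L):(i0 + 1L)]
  if (any(tri <= 0)) return(bad("non-positive intensity at the peak"))
  lt <- log(tri)
  h1 <- wl[i0] - wl[i0 - 1L]; h2 <- wl[i0 + 1L] - wl[i0]
  # vertex of the log-parabola through the three top points
  dd <- (lt[3] - lt[2]) / h2 - (lt[2] - lt[1]) / h1
  curv <- 2 * dd / (h1 + h2)
  if (curv >= 0) return(bad("no curvature at the peak"))
  slope0 <- ((lt[3] - lt[2]) / h2 * h1 + (lt[2] - lt[1]) / h1 * h2) / (h1 + h2)
  center <- wl[i0] - slope0 / curv
  amp <- exp(lt[2] - slope0^2 / (2 * curv))

  fit_side <- function(mask) {
    xs <- wl[mask] - center; ys <- it[mask]
    keep <- ys > 1e-9 * amp
    xs <- xs[keep]; ys <- ys[keep]
    if (length(xs) < 3L) return(list(sigma = NA_real_, ok = FALSE, it = 0L))
    # initial scale from the point nearest half maximum
    j <- which.min(abs(ys - amp / 2))
    sig <- abs(xs[j]) / sqrt(max(log(amp / ys[j]), 1e-6))
    if (!is.finite(sig) || sig <= 0) sig <- stats::sd(xs)
    sse <- function(s) sum((ys - amp * exp(-xs^2 / s^2))^2)
    f_old <- sse(sig)
    iters <- 0L
    for (iter in seq_len(max_iter)) {
      iters <- iter
      m <- amp * exp(-xs^2 / sig^2)
      dm <- m * (2 * xs^2 / sig^3)
      d2m <- dm * (2 * xs^2 / sig^3) - 3 * dm / sig
      r <- ys - m
      g1 <- -2 * sum(r * dm)                 # d SSE / d sigma
      g2 <- 2 * sum(dm^2) - 2 * sum(r * d2m) # d2 SSE / d sigma2
      if (!is.finite(g1) || !is.finite(g2) || g2 <= 0)
        return(list(sigma = sig, ok = FALSE, it = iters))
      step <- g1 / g2
      # damped update: halve the step while the residual increases
      lam <- 1
      repeat {
        cand <- sig - lam * step
        if (cand > 0 && sse(cand) <= f_old * (1 + 1e-12)) break
        lam <- lam / 2
        if (lam < 1e-8) break
      }
      sig_new <- max(sig - lam * step, .Machine$double.eps)
      moved <- abs(sig_new - sig)
      sig <- sig_new
      f_old <- sse(sig)
      if (moved < tol * (1 + sig)) return(list(sigma = sig, ok = TRUE, it = iters))
    }
    list(sigma = sig, ok = FALSE, it = iters)
  }
  left <- fit_side(wl < center)
  right <- fit_side(wl > center)
  structure(
    list(center = center, sigma_left = left$sigma,
         sigma_right = right$sigma, amplitude = amp,
         converged = isTRUE(left$ok) && isTRUE(right$ok),
         iterations = max(left$it, right$it)),
    class = "skew_gaussian_fit")
}

#' @export
print.skew_gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "Skew-Gaussian fit: center %.6g nm, sigma (left, right) = (%.6g, %.6g) nm, %s\n",
    x$center, x$sigma_left, x$sigma_right,
    if (x$converged) sprintf("converged in %d iterations", x$iterations)
    else "NOT converged"))
  invisible(x)
}

#' Method C: skew-Gaussian weighted centroid
#'
#' Weighted centroid as in [method_b()] but with the weight taken from a
#' fitted piecewise (skew) Gaussian source profile, accounting for the
#' asymmetry of a real broadband source.
#'
#' @inheritParams method_a
#' @param fit A converged [fit_skew_gaussian()] result.
#' @return A [phase_estimate()].
#' @export
method_c <- function(spec, config, fit) {
  stopifnot(inherits(spec, "spectrum"), inherits(fit, "skew_gaussian_fit"))
  if (!isTRUE(fit$converged))
    stop("skew-Gaussian fit did not converge; cannot weight", call. = FALSE)
  xs <- spec$wavelengths - fit$center
  s <- ifelse(xs < 0, fit$sigma_left, fit$sigma_right)
  w <- exp(-xs^2 / s^2)
  stat <- .weighted_centroid(spec, config, w)
  phase_estimate("C", stat,
                 diagnostics = list(converged = TRUE,
                                    sigma_left = fit$sigma_left,
                                    sigma_right = fit$sigma_right))
}

#' Method D: centroid weighted by the measured source spectrum
#'
#' Weighted centroid with the weight given directly by the recorded source
#' profile (scaled to maximum 1), with no shape assumption at all.
#'
#' @inheritParams method_a
#' @param source Source [spectrum()] on the same grid as `spec`.
#' @return A [phase_estimate()].
#' @export
method_d <- function(spec, config, source) {
  stopifnot(inherits(spec, "spectrum"), inherits(source, "spectrum"))
  if (length(source$wavelengths) != length(spec$wavelengths) ||
      any(abs(source$wavelengths - spec$wavelengths) >
          1e-9 * config$lambda0))
    stop("source and spectrum grids do not match", call. = FALSE)
  m <- max(source$intensities)
  if (m <= 0) stop("source spectrum has zero intensity", call. = FALSE)
  stat <- .weighted_centroid(spec, config, source$intensities / m)
  phase_estimate("D", stat, diagnostics = list(converged = TRUE))
}

# envelope-weighted sums shared by the phase-from-intensity estimators
.phase_sums <- function(nspec, config = NULL) {
  w <- nspec$w
  out <- list(Sa = sum(w^2), Sb = sum(w * nspec$y))
  if (!is.null(config))
    out$Sc <- sum(w * (config$k * nspec$x) * nspec$y)
  out
}

#' Maximum-likelihood phase estimate
#'
#' Solves the estimating equation for the phase of the interference model:
#' with `w` the envelope weights and `kx` the coupling phase across the
#' grid, the estimate is a root of
#' \deqn{\sum_i (1 - \cos(kx_i + \delta))\sin(kx_i + \delta) w_i^2 =
#'   \sum_i y_i \sin(kx_i + \delta) w_i,}
#' which is exactly the stationarity condition of the least-squares
#' objective `sum((y_i - (1 - cos(kx_i + delta)) w_i)^2)`.  The bracket is
#' scanned for descending-to-ascending sign changes of the objective
#' derivative (i.e. local minima); each is polished with
#' [stats::uniroot()] and the root with the smallest objective is
#' returned.
#'
#' @param nspec A [normalize_spectrum()] result.
#' @param config An [optical_config()].
#' @param bracket Search interval for the phase (rad), within `(-pi, pi)`.
#' @param n_scan Number of scan subintervals used to locate sign changes.
#' @return A [phase_estimate()] with `delta_hat` set.  If the bracket
#'   contains no minimum of the objective an error of class
#'   `"wmchar_no_root"` is thrown with the scan diagnostics attached.
#' @export
ml_estimate <- function(nspec, config, bracket = c(-1.5, 1.5),
                        n_scan = 400L) {
  .check_nspec(nspec)
  stopifnot(inherits(config, "optical_config"),
            length(bracket) == 2L, bracket[1] < bracket[2])
  if (bracket[1] <= -pi || bracket[2] >= pi)
    stop("bracket must lie within (-pi, pi)", call. = FALSE)
  kx <- config$k * nspec$x
  w <- nspec$w; y <- nspec$y
  score <- function(d) {
    s <- sin(kx + d)
    sum((1 - cos(kx + d)) * s * w^2) - sum(y * s * w)
  }
  objective <- function(d) sum((y - (1 - cos(kx + d)) * w)^2)
  dg <- seq(bracket[1], bracket[2], length.out = n_scan + 1L)
  gv <- vapply(dg, score, numeric(1))
  cross <- which(gv[-length(gv)] < 0 & gv[-1] >= 0)  # minima of the objective
  if (length(cross) == 0L) {
    cond <- structure(
      class = c("wmchar_no_root", "error", "condition"),
      list(message = "no root of the estimating equation in the bracket",
           call = sys.call(),
           diagnostics = list(bracket = bracket,
                              score_range = range(gv))))
    stop(cond)
  }
  roots <- vapply(cross, function(i) {
    stats::uniroot(score, lower = dg[i], upper = dg[i + 1L],
                   tol = 1e-12)$root
  }, numeric(1))
  objs <- vapply(roots, objective, numeric(1))
  best <- which.min(objs)
  phase_estimate("ml", roots[best], delta_hat = roots[best],
                 diagnostics = list(converged = TRUE, roots = roots,
                                    objective = objs[best],
                                    residual = score(roots[best])))
}

#' Classical intensity-ratio phase estimate
#'
#' In the classical limit (`delta` much larger than the coupling phase
#' `kx` across the band) the estimating equation reduces to the intensity
#' ratio inversion
#' \deqn{1 - \cos\delta = \sum_i w_i y_i / \sum_i w_i^2,}
#' solved in closed form.  The arccosine is even, so the returned phase
#' lies in `[0, pi]`; the sign must be resolved externally (e.g. from the
#' sign of the [method_b()] statistic on the same spectrum).
#'
#' @inheritParams ml_estimate
#' @param tol Tolerance for the admissible ratio interval `[0, 2]`.
#' @return A [phase_estimate()] with `delta_hat` in `[0, pi]`.  A ratio
#'   outside `[0, 2]` beyond `tol` throws an error of class
#'   `"wmchar_out_of_model"`.
#' @export
classical_estimate <- function(nspec, tol = 1e-6) {
  .check_nspec(nspec)
  s <- .phase_sums(nspec)
  r <- s$Sb / s$Sa
  if (r < -tol || r > 2 + tol) {
    cond <- structure(
      class = c("wmchar_out_of_model", "error", "condition"),
      list(message = sprintf(
        "intensity ratio %.6g outside the admissible interval [0, 2]", r),
        call = sys.call(), diagnostics = list(ratio = r)))
    stop(cond)
  }
  r <- min(max(r, 0), 2)
  d <- acos(1 - r)
  phase_estimate("classical", d, delta_hat = d,
                 diagnostics = list(converged = TRUE, ratio = r))
}

#' Method E: transition-equation phase estimate
#'
#' Solves the implicit transition equation bridging the weak-value and
#' classical readout regimes.  With `z = tan(delta / 2)` and the envelope
#' weighted sums `S_a = sum(w^2)`, `S_b = sum(w y)`,
#' `S_c = sum(w (k x) y)`, the equation
#' \deqn{\frac{2z^2}{1+z^2} S_a - S_b = \frac{2z}{1-z^2} S_c}
#' is cleared of denominators to the quartic
#' `(S_b - 2 S_a) z^4 - 2 S_c z^3 + 2 S_a z^2 - 2 S_c z - S_b = 0`.
#' All real roots with `|z| < 1` are admissible; among those whose sign
#' matches `sign(S_c)` the smallest in magnitude is selected (continuity
#' with `delta -> 0` and with the weak limit), and the phase is
#' `delta_hat = 2 atan(z)`.
#'
#' @inheritParams ml_estimate
#' @return A [phase_estimate()] with `delta_hat` set and the full root set
#'   in the diagnostics.  If no admissible root exists an error of class
#'   `"wmchar_no_root"` is thrown carrying the root set.
#' @export
method_e <- function(nspec, config) {
  .check_nspec(nspec)
  stopifnot(inherits(config, "optical_config"))
  s <- .phase_sums(nspec, config)
  if (s$Sb == 0 && s$Sc == 0)
    return(phase_estimate("E", 0, delta_hat = 0,
                          diagnostics = list(converged = TRUE, z = 0,
                                             roots = complex(0))))
  coefs <- c(-s$Sb, -2 * s$Sc, 2 * s$Sa, -2 * s$Sc, s$Sb - 2 * s$Sa)
  roots <- polyroot(coefs)
  scale <- max(abs(roots), 1)
  real_roots <- Re(roots[abs(Im(roots)) <= 1e-8 * scale])
  admissible <- real_roots[abs(real_roots) < 1 - 1e-9]
  if (s$Sc != 0) {
    signed <- admissible[sign(admissible) == sign(s$Sc)]
    if (length(signed) > 0L) admissible <- signed
  }
  if (length(admissible) == 0L) {
    cond <- structure(
      class = c("wmchar_no_root", "error", "condition"),
      list(message = "transition equation has no admissible root |z| < 1",
           call = sys.call(),
           diagnostics = list(roots = roots, Sa = s$Sa, Sb = s$Sb,
                              Sc = s$Sc)))
    stop(cond)
  }
  z <- admissible[which.min(abs(admissible))]
  d <- 2 * atan(z)
  phase_estimate("E", d, delta_hat = d,
                 diagnostics = list(converged = TRUE, z = z, roots = roots,
                                    Sa = s$Sa, Sb = s$Sb, Sc = s$Sc))
}
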