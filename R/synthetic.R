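#' Specification of a stepped phase ramp
#'
#' Describes the stepped-ramp acquisition protocol used to calibrate and
#' compare characterization methods: the phase is stepped by a variable
#' retarder (Soleil-Babinet compensator) in increments of `step` rad, and
#' `reps_per_step` spectra are recorded at each step.
#'
#' @param delta_start,delta_end First and last phase (rad).
#' @param step Phase increment (rad), default 0.003.
#' @param reps_per_step Replicate spectra per step.
#' @param noise_sigma Additive detector noise, as a fraction of the source
#'   peak intensity (see [generate_ramp()]).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param source_shape `"gaussian"`, a
#'   `list(type = "skew_gaussian", sigma1 =, sigma2 =)` with the left and
#'   right envelope scales in nm, or a [spectrum()] with an empirical
#'   source profile.
#' @return An object of class `"ramp_spec"`.
#' @export
ramp_spec <- function(delta_start = -0.45, delta_end = 0.45, step = 0.003,
                      reps_per_step = 50L, noise_sigma = 1e-4, seed = 1L,
                      source_shape = "gaussian") {
  stopifnot(is.numeric(step), step > 0, delta_end > delta_start,
            reps_per_step >= 1L, noise_sigma >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(delta_start = delta_start, delta_end = delta_end,
                 step = step, reps_per_step = as.integer(reps_per_step),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 source_shape = source_shape),
            class = "ramp_spec")
}

# envelope vector (max 1) for a configured source shape on a grid
.source_envelope <- function(shape, config, grid) {
  x <- grid - config$lambda0
  if (is.character(shape) && identical(shape, "gaussian"))
    return(exp(-x^2 / config$sigma_lambda^2))
  if (is.list(shape) && identical(shape$type, "skew_gaussian")) {
    stopifnot(is.numeric(shape$sigma1), shape$sigma1 > 0,
              is.numeric(shape$sigma2), shape$sigma2 > 0)
    s <- ifelse(x < 0, shape$sigma1, shape$sigma2)
    return(exp(-x^2 / s^2))
  }
  if (inherits(shape, "spectrum")) {
    env <- stats::approx(shape$wavelengths, shape$intensities, xout = grid,
                         rule = 2)$y
    m <- max(env)
    if (m <= 0) stop("empirical source profile has zero intensity",
                     call. = FALSE)
    return(env / m)
  }
  stop("unknown source_shape", call. = FALSE)
}

#' Generate a noisy stepped phase ramp
#'
#' Emulates the stepped-ramp experiment: for each phase step,
#' `reps_per_step` readout spectra are simulated from the interference
#' model and corrupted with additive Gaussian detector noise of standard
#' deviation `noise_sigma * amplitude * max(envelope)` (i.e. referred to
#' the source peak intensity, independent of how dark the fringe is),
#' clipped at zero.  Output is deterministic for a fixed seed.
#'
#' @param rspec A [ramp_spec()].
#' @param config An [optical_config()].
#' @param grid Wavelength grid (nm).
#' @param amplitude Source peak intensity scale.
#' @return An object of class `"wm_ramp"`: a list with `steps` (a list of
#'   `list(delta, spectra)`), `source` (the noiseless source [spectrum()]
#'   on the same grid), `spec` (the ramp specification) and `config`.
#' @export
generate_ramp <- function(rspec, config, grid = default_grid(config),
                          amplitude = 1) {
  stopifnot(inherits(rspec, "ramp_spec"), inherits(config, "optical_config"))
  set.seed(rspec$seed)
  env <- .source_envelope(rspec$source_shape, config, grid)
  x <- grid - config$lambda0
  deltas <- seq(rspec$delta_start, rspec$delta_end, by = rspec$step)
  noise_sd <- rspec$noise_sigma * amplitude * max(env)
  steps <- lapply(deltas, function(d) {
    base <- amplitude * (1 - cos(config$k * x + d)) * env
    spectra <- lapply(seq_len(rspec$reps_per_step), function(r) {
      it <- base
      if (noise_sd > 0) it <- pmax(base + stats::rnorm(length(base),
                                                       sd = noise_sd), 0)
      spectrum(grid, it, label = sprintf("delta=%.6g rep=%d", d, r))
    })
    list(delta = d, spectra = spectra)
  })
  structure(list(steps = steps,
                 source = spectrum(grid, amplitude * env, label = "source"),
                 spec = rspec, config = config),
            class = "wm_ramp")
}

#' @export
print.wm_ramp <- function(x, ...) {
  cat(sprintf(
    "Phase ramp: %d steps of %.4g rad in [%.4g, %.4g], %d reps/step, noise %.3g\n",
    length(x$steps), x$spec$step, x$spec$delta_start, x$spec$delta_end,
    x$spec$reps_per_step, x$spec$noise_sigma))
  invisible(x)
}

#' Specification of a sucrose hydrolysis monitoring run
#'
#' Describes the acid-catalysed sucrose inversion experiment monitored by
#' the weak measurement polarimeter.  Sucrose hydrolyses to glucose +
#' fructose (pseudo-first-order in excess water with acid catalyst); the
#' products' net specific rotation has the opposite sign to sucrose, so
#' the optical rotation, and with it the polarization phase difference,
#' drifts and inverts as the reaction proceeds.
#'
#' The default specific rotations are literature-typical values
#' (degrees mL / (g dm)): +66.5 sucrose, +52.7 glucose, -92.4 fructose.
#' Per gram of hydrolysed sucrose, 180.16/342.30 grams of each product are
#' formed.  The observed rotation for path length `l` (dm) and
#' concentrations `c` (g/L) is `l * sum([alpha]_i c_i) / 1000` degrees,
#' and the polarization phase is
#' `delta(t) = delta0 + rotation_to_delta * rotation(t) * pi / 180`.
#'
#' @param concentrations Initial sucrose concentrations (g/L).
#' @param rate_constant Pseudo-first-order hydrolysis rate (1/s).
#' @param duration,dt Monitoring duration and sampling interval (s).
#' @param delta0 Working-point phase offset set by the compensator (rad).
#' @param rotation_to_delta Dimensionless gain from optical rotation (rad)
#'   to polarization phase difference (rad).  A rotation of the linear
#'   polarization by `theta` advances the relative phase of its two
#'   circular components by `2 theta`, hence the default of 2.
#' @param specific_rotations Named numeric vector with entries `sucrose`,
#'   `glucose`, `fructose` (degrees mL / (g dm)).
#' @param path_length Sample cell path length (dm).
#' @param noise_sigma Additive detector noise, fraction of source peak.
#' @param seed Integer seed.
#' @param source_shape As in [ramp_spec()].
#' @return An object of class `"hydrolysis_spec"`.
#' @export
hydrolysis_spec <- function(concentrations = c(2, 5, 10, 20, 30),
                            rate_constant = 4e-4,
                            duration = 10800, dt = 120,
                            delta0 = 0.1, rotation_to_delta = 2,
                            specific_rotations = c(sucrose = 66.5,
                                                   glucose = 52.7,
                                                   fructose = -92.4),
                            path_length = 1, noise_sigma = 1e-4,
                            seed = 1L, source_shape = "gaussian") {
  stopifnot(all(concentrations > 0), rate_constant >= 0, duration > 0,
            dt > 0, rotation_to_delta != 0, path_length > 0,
            noise_sigma >= 0,
            all(c("sucrose", "glucose", "fructose") %in%
                  names(specific_rotations)))
  structure(list(concentrations = concentrations,
                 rate_constant = rate_constant, duration = duration,
                 dt = dt, delta0 = delta0,
                 rotation_to_delta = rotation_to_delta,
                 specific_rotations = specific_rotations,
                 path_length = path_length, noise_sigma = noise_sigma,
                 seed = as.integer(seed), source_shape = source_shape),
            class = "hydrolysis_spec")
}

# stoichiometric mass ratio: grams of each monosaccharide per gram sucrose
.invert_mass_ratio <- 180.16 / 342.30

#' Net optical rotation during sucrose hydrolysis
#'
#' Closed-form rotation (degrees) at time `t` for initial sucrose
#' concentration `c0` (g/L) under the pseudo-first-order kinetics and
#' specific rotations of `hspec`.
#'
#' @param t Time (s), vectorized.
#' @param c0 Initial sucrose concentration (g/L).
#' @param hspec A [hydrolysis_spec()].
#' @return Rotation in degrees (same length as `t`).
#' @export
hydrolysis_rotation <- function(t, c0, hspec) {
  stopifnot(inherits(hspec, "hydrolysis_spec"))
  sr <- hspec$specific_rotations
  cs <- c0 * exp(-hspec$rate_constant * t)
  cprod <- .invert_mass_ratio * (c0 - cs)
  hspec$path_length *
    (sr[["sucrose"]] * cs + (sr[["glucose"]] + sr[["fructose"]]) * cprod) /
    1000
}

#' Phase difference during sucrose hydrolysis
#'
#' @inheritParams hydrolysis_rotation
#' @return Phase `delta(t)` (rad).
#' @export
hydrolysis_delta <- function(t, c0, hspec) {
  hspec$delta0 +
    hspec$rotation_to_delta * hydrolysis_rotation(t, c0, hspec) * pi / 180
}

#' Generate synthetic hydrolysis monitoring spectra
#'
#' For each initial concentration, simulates the time series of readout
#' spectra as the phase drifts with the hydrolysis kinetics, with the same
#' detector noise model as [generate_ramp()].  Ground-truth phases are
#' returned alongside the spectra.
#'
#' @param hspec A [hydrolysis_spec()].
#' @param config An [optical_config()].
#' @param grid Wavelength grid (nm).
#' @param amplitude Source peak intensity scale.
#' @return An object of class `"wm_hydrolysis"`: list with `series` (one
#'   entry per concentration: `concentration`, `time`, `delta_true`,
#'   `spectra`), `source`, `spec`, `config`.
#' @export
generate_hydrolysis <- function(hspec, config, grid = default_grid(config),
                                amplitude = 1) {
  stopifnot(inherits(hspec, "hydrolysis_spec"),
            inherits(config, "optical_config"))
  set.seed(hspec$seed)
  env <- .source_envelope(hspec$source_shape, config, grid)
  x <- grid - config$lambda0
  noise_sd <- hspec$noise_sigma * amplitude * max(env)
  times <- seq(0, hspec$duration, by = hspec$dt)
  series <- lapply(hspec$concentrations, function(c0) {
    dts <- hydrolysis_delta(times, c0, hspec)
    spectra <- lapply(seq_along(times), function(i) {
      base <- amplitude * (1 - cos(config$k * x + dts[i])) * env
      it <- base
      if (noise_sd > 0) it <- pmax(base + stats::rnorm(length(base),
                                                       sd = noise_sd), 0)
      spectrum(grid, it, time = times[i],
               label = sprintf("c0=%g g/L", c0))
    })
    list(concentration = c0, time = times, delta_true = dts,
         spectra = spectra)
  })
  structure(list(series = series,
                 source = spectrum(grid, amplitude * env, label = "source"),
                 spec = hspec, config = config),
            class = "wm_hydrolysis")
}

#' @export
print.wm_hydrolysis <- function(x, ...) {
  cat(sprintf(
    "Hydrolysis monitoring: c0 = %s g/L, %d frames over %.4g s, delta0 = %.4g rad\n",
    paste(x$spec$concentrations, collapse = ", "),
    length(x$series[[1]]$time), x$spec$duration, x$spec$delta0))
  invisible(x)
}

#' Concentration linearity of a characterization method on hydrolysis data
#'
#' The monitoring figure of merit: for each initial concentration the
#' change of the method's statistic over the full reaction,
#' `Delta = mean(statistic over the last n_avg frames) - mean(over the
#' first n_avg frames)`, regressed against the initial concentration.
#' A method whose statistic responds linearly to phase across the whole
#' rotation excursion yields a straight line; a method driven outside its
#' linear measurement range shows curvature, concentrated at the highest
#' concentrations.
#'
#' @param sim A [generate_hydrolysis()] result.
#' @param method Method identifier, see [estimate_phase()].
#' @param aux Method-specific inputs; the simulation's source spectrum is
#'   supplied automatically where needed.
#' @param n_avg Number of initial/final frames averaged per end point.
#' @return A list with `concentration`, `dstat` (statistic change per
#'   concentration), `r_squared` and `residuals` of the linear fit over
#'   all concentrations, `fit` coefficients `(intercept, slope)`, and the
#'   low-concentration extrapolation diagnostics `r_squared_low` (fit
#'   excluding the highest concentration) and `extrapolation_residuals`
#'   (deviation of every point from that low-concentration line) — the
#'   direct probe of linearity that holds up to, but not beyond, a given
#'   concentration.
#' @export
monitor_hydrolysis <- function(sim, method, aux = list(), n_avg = 5L) {
  stopifnot(inherits(sim, "wm_hydrolysis"))
  config <- sim$config
  if (is.null(aux$source) &&
      method %in% c("C", "D", "E", "classical", "ml"))
    aux$source <- sim$source
  if (method == "C" && is.null(aux$fit))
    aux$fit <- fit_skew_gaussian(aux$source %||% sim$source)
  conc <- vapply(sim$series, `[[`, numeric(1), "concentration")
  dstat <- vapply(sim$series, function(ser) {
    n <- length(ser$spectra)
    n_avg <- min(n_avg, floor(n / 2))
    stat_at <- function(idx) {
      mean(vapply(ser$spectra[idx], function(sp) {
        tryCatch(estimate_phase(sp, method, config, aux)$statistic,
                 error = function(e) NA_real_)
      }, numeric(1)), na.rm = TRUE)
    }
    stat_at(seq(n - n_avg + 1L, n)) - stat_at(seq_len(n_avg))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, conc), dstat)
  ssr <- sum(fit$residuals^2)
  sst <- sum((dstat - mean(dstat))^2)
  low <- seq_len(length(conc) - 1L)
  fit_low <- stats::lm.fit(cbind(1, conc[low]), dstat[low])
  pred_low <- fit_low$coefficients[[1]] + fit_low$coefficients[[2]] * conc
  ssr_low <- sum(fit_low$residuals^2)
  sst_low <- sum((dstat[low] - mean(dstat[low]))^2)
  list(concentration = conc, dstat = dstat,
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
       residuals = fit$residuals,
       fit = stats::setNames(fit$coefficients, c("intercept", "slope")),
       r_squared_low = if (sst_low > 0) 1 - ssr_low / sst_low else NA_real_,
       extrapolation_residuals = dstat - pred_low,
       method = method)
}
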