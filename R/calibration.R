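#' Apply a characterization method to one spectrum
#'
#' Dispatcher used by the calibration protocol and the command line
#' interface.  Centroid methods return their raw statistic; the
#' phase-from-intensity methods return the estimated phase as statistic.
#'
#' @param spec A [spectrum()].
#' @param method One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"classical"`,
#'   `"ml"`.
#' @param config An [optical_config()].
#' @param aux Named list of method-specific inputs: `source` (a
#'   [spectrum()], required by methods C and D and used as envelope weight
#'   for E/classical/ml when present), `fit` (a [fit_skew_gaussian()]
#'   result for method C; fitted from `source` if absent),
#'   `reference_centroid` (method A), `bracket` (ml).
#' @return A [phase_estimate()].
#' @export
estimate_phase <- function(spec, method, config, aux = list()) {
  method <- match.arg(method, c("A", "B", "C", "D", "E", "classical", "ml"))
  switch(method,
    A = method_a(spec, config,
                 reference_centroid = aux$reference_centroid %||%
                   config$lambda0),
    B = method_b(spec, config),
    C = {
      fit <- aux$fit
      if (is.null(fit)) {
        if (is.null(aux$source))
          stop("method C needs `aux$source` or a pre-computed `aux$fit`",
               call. = FALSE)
        fit <- fit_skew_gaussian(aux$source)
      }
      method_c(spec, config, fit)
    },
    D = {
      if (is.null(aux$source))
        stop("method D needs `aux$source`", call. = FALSE)
      method_d(spec, config, aux$source)
    },
    E = method_e(normalize_spectrum(spec, config, source = aux$source),
                 config),
    classical = classical_estimate(
      normalize_spectrum(spec, config, source = aux$source)),
    ml = ml_estimate(normalize_spectrum(spec, config, source = aux$source),
                     config,
                     bracket = aux$bracket %||% c(-1.5, 1.5)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a calibration curve from a stepped phase ramp
#'
#' Runs one characterization method over every replicate spectrum of a
#' stepped phase ramp (known phase per step), collects the per-step mean
#' and standard deviation of the statistic, detects the linear window of
#' the mean curve and fits the calibration line over it.
#'
#' Steps on which the estimator fails for more than half the replicates
#' are excluded from the curve (and recorded in the result).
#'
#' @param steps Either a `"wm_ramp"` object from [generate_ramp()] or a
#'   list of `list(delta = <rad>, spectra = <list of spectrum>)`.
#' @param method Method identifier, see [estimate_phase()].
#' @param config An [optical_config()].
#' @param aux Method-specific inputs, see [estimate_phase()].  For a
#'   `"wm_ramp"` input the ramp's source spectrum is supplied
#'   automatically for methods C and D.
#' @param tolerance Linearity tolerance passed to [linear_range()].
#' @return An object of class `"calibration_curve"` with fields `deltas`,
#'   `statistics` (per-step means), `sigma_s` (per-step standard
#'   deviations), `slope`, `intercept`, `r_squared` (over the linear
#'   window), `linear_range` (phase window, rad), `degenerate` flag,
#'   `excluded` (deltas of excluded steps) and `method`.
#' @export
build_calibration <- function(steps, method, config, aux = list(),
                              tolerance = 0.05) {
  if (inherits(steps, "wm_ramp")) {
    # the recorded source profile doubles as centroid weight (C, D) and as
    # envelope weight for the intensity-based estimators (non-Gaussian
    # sources require the measured profile in the estimating equations)
    if (is.null(aux$source) &&
        method %in% c("C", "D", "E", "classical", "ml"))
      aux$source <- steps$source
    steps <- steps$steps
  }
  if (method %in% c("C", "D") && is.null(aux$source) && is.null(aux$fit))
    stop("method ", method, " needs a source spectrum in `aux$source`",
         call. = FALSE)
  if (length(steps) < 3L)
    stop("need at least 3 ramp steps to calibrate", call. = FALSE)
  if (any(vapply(steps, function(s) length(s$spectra), integer(1)) < 2L))
    stop("need at least 2 replicates per step", call. = FALSE)
  if (method == "C" && is.null(aux$fit) && !is.null(aux$source))
    aux$fit <- fit_skew_gaussian(aux$source)
  deltas <- vapply(steps, `[[`, numeric(1), "delta")
  if (any(diff(deltas) <= 0))
    stop("step phases must be strictly increasing", call. = FALSE)
  per_step <- lapply(steps, function(s) {
    vapply(s$spectra, function(sp) {
      tryCatch(estimate_phase(sp, method, config, aux)$statistic,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  frac_ok <- vapply(per_step, function(v) mean(!is.na(v)), numeric(1))
  excluded <- deltas[frac_ok < 0.5]
  if (length(excluded) > 0L)
    message(sprintf(
      "method %s: excluded %d step(s) with > 50%% estimator failures",
      method, length(excluded)))
  keep <- frac_ok >= 0.5
  deltas <- deltas[keep]; per_step <- per_step[keep]
  if (length(deltas) < 3L)
    stop("fewer than 3 usable steps after exclusions", call. = FALSE)
  means <- vapply(per_step, function(v) mean(v, na.rm = TRUE), numeric(1))
  sds <- vapply(per_step, function(v) stats::sd(v[!is.na(v)]), numeric(1))
  win <- .linear_window(deltas, means, tolerance)
  inw <- deltas >= win$range[1] & deltas <= win$range[2]
  fit <- stats::lm.fit(cbind(1, deltas[inw]), means[inw])
  slope <- fit$coefficients[[2]]
  intercept <- fit$coefficients[[1]]
  ssr <- sum(fit$residuals^2)
  sst <- sum((means[inw] - mean(means[inw]))^2)
  structure(
    list(deltas = deltas, statistics = means, sigma_s = sds,
         slope = slope, intercept = intercept,
         r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
         linear_range = win$range, degenerate = win$degenerate,
         tolerance = tolerance, excluded = excluded, method = method),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [method %s]: %d steps, delta in [%.4g, %.4g] rad\n",
              x$method, length(x$deltas), min(x$deltas), max(x$deltas)))
  cat(sprintf("  linear range [%.4g, %.4g] rad (width %.4g)%s\n",
              x$linear_range[1], x$linear_range[2],
              diff(x$linear_range),
              if (x$degenerate) " DEGENERATE" else ""))
  cat(sprintf("  slope %.6g / rad, intercept %.6g, R^2 %.6g\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

# Widest contiguous window that contains the center of the phase span and
# in which every point deviates from the window's own least-squares line
# by at most `tolerance` times the window's statistic span.
.linear_window <- function(deltas, stats_, tolerance) {
  n <- length(deltas)
  centre <- which.min(abs(deltas - mean(range(deltas))))
  best <- NULL; best_width <- -Inf
  for (i in seq_len(centre)) {
    for (j in seq(centre, n)) {
      if (j - i < 2L) next
      idx <- i:j
      d <- deltas[idx]; s <- stats_[idx]
      fit <- stats::lm.fit(cbind(1, d), s)
      span <- diff(range(s))
      if (max(abs(fit$residuals)) <= tolerance * span) {
        width <- d[length(d)] - d[1]
        if (width > best_width) { best_width <- width; best <- c(d[1], d[length(d)]) }
      }
    }
  }
  if (is.null(best))
    list(range = rep(deltas[centre], 2), degenerate = TRUE)
  else
    list(range = best, degenerate = FALSE)
}

#' Linear measurement range of a calibration curve
#'
#' The widest contiguous phase window containing the center of the curve
#' in which every point deviates from the window's own least-squares line
#' by at most `tolerance` times the statistic span of the window.
#'
#' @param curve A [build_calibration()] result.
#' @param tolerance Allowed fractional deviation (default 5%).
#' @return Numeric vector `c(lo, hi)` (rad) with attribute `"degenerate"`
#'   set to `TRUE` when no 3-point window satisfies the criterion.
#' @export
linear_range <- function(curve, tolerance = 0.05) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (length(curve$deltas) < 3L)
    stop("need at least 3 steps", call. = FALSE)
  win <- .linear_window(curve$deltas, curve$statistics, tolerance)
  structure(win$range, degenerate = win$degenerate)
}

#' Phase resolution of a calibrated method
#'
#' The smallest detectable phase change, computed as three times the
#' typical per-step noise of the statistic divided by the calibration
#' slope: `sigma_alpha = 3 * median(sigma_s) / |slope|`, with the median
#' taken over the steps inside the linear window.
#'
#' @param curve A [build_calibration()] result.
#' @return Resolution (rad).
#' @export
resolution <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope == 0)
    stop("resolution undefined: zero calibration slope", call. = FALSE)
  inw <- curve$deltas >= curve$linear_range[1] &
    curve$deltas <= curve$linear_range[2]
  3 * stats::median(curve$sigma_s[inw]) / abs(curve$slope)
}

#' Compare characterization methods on one ramp
#'
#' Builds a calibration curve per method on the identical input set and
#' summarizes resolution and linear measurement range, the comparison
#' protocol of the stepped-ramp experiment.  Per-method failures are
#' recorded in the report rather than raised.
#'
#' @inheritParams build_calibration
#' @param methods Character vector of method identifiers.
#' @return A list of `"method_report"` objects (class
#'   `"method_comparison"`), each with fields `method`, `resolution`,
#'   `measurement_range` (window width, rad), `curve` and `error`.
#' @export
compare_methods <- function(steps, methods = c("A", "B", "C", "D", "E"),
                            config, aux = list(), tolerance = 0.05) {
  reports <- lapply(methods, function(m) {
    res <- tryCatch({
      curve <- build_calibration(steps, m, config, aux = aux,
                                 tolerance = tolerance)
      list(method = m, resolution = resolution(curve),
           measurement_range = diff(curve$linear_range),
           curve = curve, error = NA_character_)
    }, error = function(e) {
      list(method = m, resolution = NA_real_,
           measurement_range = NA_real_, curve = NULL,
           error = conditionMessage(e))
    })
    structure(res, class = "method_report")
  })
  structure(reports, class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Method comparison\n")
  cat(sprintf("  %-10s %-14s %-18s\n", "method", "resolution", "range (rad)"))
  for (r in x) {
    if (is.na(r$resolution) && !is.na(r$error))
      cat(sprintf("  %-10s failed: %s\n", r$method, r$error))
    else
      cat(sprintf("  %-10s %-14.4g %-18.4g\n", r$method, r$resolution,
                  r$measurement_range))
  }
  invisible(x)
}

#' Write a method comparison report to CSV
#'
#' Writes one row per method with a stable column order:
#' `method, resolution_rad, measurement_range_rad, slope, r_squared,
#' n_steps, seed`.  Reruns on identical inputs and seed produce
#' byte-identical files.
#'
#' @param reports A `"method_comparison"` (or list of `"method_report"`).
#' @param path Output CSV path.
#' @param seed Seed recorded in the report (use the generator's seed).
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, seed = NA_integer_) {
  if (length(reports) == 0L) stop("empty report list", call. = FALSE)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
  lines <- "method,resolution_rad,measurement_range_rad,slope,r_squared,n_steps,seed"
  for (r in reports) {
    slope <- if (is.null(r$curve)) NA_real_ else r$curve$slope
    r2 <- if (is.null(r$curve)) NA_real_ else r$curve$r_squared
    n <- if (is.null(r$curve)) 0L else length(r$curve$deltas)
    lines <- c(lines, paste(r$method, fmt(r$resolution),
                            fmt(r$measurement_range), fmt(slope), fmt(r2),
                            n, ifelse(is.na(seed), "NA", seed), sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}
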