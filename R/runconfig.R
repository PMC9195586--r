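#' Read a run configuration file
#'
#' Parses the flat key/value configuration format used by the command
#' line interface: one `key = value` (or `key: value`) pair per line,
#' `#` comments, blank lines ignored.  Unknown keys are errors, so typos
#' in method options fail loudly.
#'
#' Recognized keys: `alpha`, `beta`, `k`, `lambda0`, `fwhm`,
#' `sigma_lambda`, `sigma_convention`, `delta_start`, `delta_end`,
#' `step`, `reps_per_step`, `noise_sigma`, `seed`, `tolerance`,
#' `methods`, `source_shape`, `sigma1`, `sigma2`, `concentrations`,
#' `rate_constant`, `duration`, `dt`, `delta0`, `rotation_to_delta`,
#' `path_length`, `grid_points`, `grid_span`, `bracket_lo`, `bracket_hi`.
#'
#' @param path Path to the configuration file.
#' @return A named list of parsed values (numeric where possible;
#'   comma-separated values become vectors) with class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  known <- c("alpha", "beta", "k", "lambda0", "fwhm", "sigma_lambda",
             "sigma_convention", "delta_start", "delta_end", "step",
             "reps_per_step", "noise_sigma", "seed", "tolerance",
             "methods", "source_shape", "sigma1", "sigma2",
             "concentrations", "rate_constant", "duration", "dt",
             "delta0", "rotation_to_delta", "path_length", "grid_points",
             "grid_span", "bracket_lo", "bracket_hi")
  character_keys <- c("sigma_convention", "methods", "source_shape")
  raw <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(raw)) {
    line <- sub("#.*$", "", raw[i])
    if (grepl("^\\s*$", line)) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*[=:](.*)$",
                                  line))[[1]]
    if (length(m) != 3L)
      stop("malformed config line ", i, ": ", raw[i], call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% known)
      stop("unknown config key `", key, "` at line ", i, call. = FALSE)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (key %in% character_keys) {
      out[[key]] <- parts
    } else {
      num <- suppressWarnings(as.numeric(parts))
      if (any(is.na(num)))
        stop("non-numeric value for `", key, "` at line ", i, call. = FALSE)
      out[[key]] <- num
    }
  }
  structure(out, class = "run_config")
}

#' Build an optical configuration from a run configuration
#'
#' @param rc A [read_run_config()] result.
#' @return An [optical_config()].
#' @export
run_config_optics <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  args <- list(alpha = rc$alpha %||% (pi / 4), beta = rc$beta %||% (pi / 4),
               k = rc$k, lambda0 = rc$lambda0 %||% 840)
  if (!is.null(rc$sigma_lambda)) args$sigma_lambda <- rc$sigma_lambda
  else args$fwhm <- rc$fwhm %||% 40
  if (!is.null(rc$sigma_convention))
    args$sigma_convention <- rc$sigma_convention
  do.call(optical_config, args)
}
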