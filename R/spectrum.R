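#' Readout spectrum
#'
#' A wavelength grid with matching intensities, the pointer readout of the
#' weak measurement system.
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param intensities Matching non-negative intensities (arbitrary units).
#' @param time Optional acquisition time (s).
#' @param label Optional character label.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths, intensities, time = NULL, label = NULL) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length", call. = FALSE)
  if (length(wavelengths) < 3L)
    stop("a spectrum needs at least 3 points", call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(!is.finite(intensities)))
    stop("wavelengths and intensities must be finite", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 time = time, label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points, %.6g-%.6g nm, peak intensity %.6g",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              max(x$intensities)))
  if (!is.null(x$label)) cat(sprintf(" [%s]", x$label))
  if (!is.null(x$time)) cat(sprintf(" @ t = %.6g s", x$time))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, intensity = x$intensities)
}

#' Read a spectrum from a two-column text file
#'
#' Parses the on-disk spectrum format: two columns, `wavelength_nm` then
#' `intensity`, comma- or tab-separated.  A header line is optional and
#' lines starting with `#` are comments.  Rows are sorted by wavelength;
#' duplicate wavelengths and malformed rows are rejected with the offending
#' line number.
#'
#' @param path Path to a CSV/TSV spectrum file.
#' @return A [spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("no data rows in ", path, call. = FALSE)
  sep <- if (grepl("\t", raw[keep[1]])) "\t" else ","
  first <- strsplit(raw[keep[1]], sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  if (has_header) keep <- keep[-1]
  wl <- numeric(length(keep)); it <- numeric(length(keep))
  for (j in seq_along(keep)) {
    fields <- strsplit(raw[keep[j]], sep, fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      stop("malformed spectrum row at line ", keep[j], " of ", path,
           call. = FALSE)
    wl[j] <- vals[1]; it[j] <- vals[2]
    if (it[j] < 0)
      stop("negative intensity at line ", keep[j], " of ", path,
           call. = FALSE)
  }
  ord <- order(wl)
  wl <- wl[ord]; it <- it[ord]
  if (any(diff(wl) == 0))
    stop("duplicate wavelengths in ", path, call. = FALSE)
  spectrum(wl, it)
}

#' Write a spectrum to a two-column CSV file
#'
#' Values are written with 12 significant digits so that a write/read
#' round trip preserves the spectrum to formatting precision.
#'
#' @param spec A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  lines <- c("wavelength_nm,intensity",
             paste(sprintf("%.12g", spec$wavelengths),
                   sprintf("%.12g", spec$intensities),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}
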