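#' Construct a spectrum tibble
#'
#' A spectrum is an ordinary tibble with columns `wavenumber` (cm^-1, strictly
#' ascending) and `value` (intensity or delta-A), carrying a `domain` attribute
#' naming what the values are. All chladyn functions accept and return this
#' shape, so spectra chain naturally through dplyr/ggplot2.
#'
#' @param wavenumber Strictly ascending numeric axis, cm^-1.
#' @param value Numeric values, same length as `wavenumber`, no NA.
#' @param domain One of "absorbance", "excitation", "emission", "delta_A".
#' @return A tibble with columns `wavenumber`, `value` and attribute `domain`.
#' @export
spectrum_tbl <- function(wavenumber, value,
                         domain = c("absorbance", "excitation", "emission", "delta_A")) {
  domain <- match.arg(domain)
  wavenumber <- as.numeric(wavenumber)
  value <- as.numeric(value)
  if (length(wavenumber) != length(value)) {
    stop("axis and values must have equal length", call. = FALSE)
  }
  if (anyNA(wavenumber) || anyNA(value)) {
    stop("spectrum must not contain NA", call. = FALSE)
  }
  if (length(wavenumber) > 1 && any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly ascending", call. = FALSE)
  }
  out <- tibble::tibble(wavenumber = wavenumber, value = value)
  attr(out, "domain") <- domain
  out
}

#' @rdname spectrum_tbl
#' @param x Object to test.
#' @export
is_spectrum <- function(x) {
  is.data.frame(x) && all(c("wavenumber", "value") %in% names(x))
}

.check_same_axis <- function(a, b, what = "spectra") {
  if (length(a$wavenumber) != length(b$wavenumber) ||
      any(abs(a$wavenumber - b$wavenumber) > 1e-9)) {
    stop(sprintf("%s are on different wavenumber axes; align them explicitly first", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write two-column text spectra
#'
#' Plain-text exchange format: optional comment lines starting with `#`, one
#' of which may declare the axis unit as `# axis: nm` or `# axis: cm-1`
#' (default cm-1), followed by two whitespace- or comma-separated columns
#' (axis, value). Wavelength input is converted to an ascending wavenumber
#' axis with the values reordered accordingly; a write/read round trip is
#' lossless to full double precision.
#'
#' @param path File path.
#' @param domain Domain tag attached to the result (see [spectrum_tbl()]).
#' @return `read_spectrum()` returns a spectrum tibble; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, domain = "absorbance") {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  axis_unit <- "cm-1"
  hdr <- grep("^\\s*#\\s*axis\\s*:", lines, value = TRUE)
  if (length(hdr) >= 1) {
    unit <- trimws(sub("^\\s*#\\s*axis\\s*:\\s*", "", hdr[[1]]))
    if (!unit %in% c("nm", "cm-1")) {
      stop(sprintf("unknown axis unit '%s' (expected nm or cm-1)", unit), call. = FALSE)
    }
    axis_unit <- unit
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[body_idx]), "[,[:space:]]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d of %s (expected 2 columns, found %d)",
                 body_idx[bad[[1]]], path, n_fields[bad[[1]]]), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f), numeric(2)))
  if (anyNA(vals)) {
    bad <- body_idx[which(colSums(is.na(vals)) > 0)[[1]]]
    stop(sprintf("non-numeric value at line %d of %s", bad, path), call. = FALSE)
  }
  axis <- vals[1, ]
  value <- vals[2, ]
  if (axis_unit == "nm") axis <- wavelength_to_wavenumber(axis)
  ord <- order(axis)
  axis <- axis[ord]
  value <- value[ord]
  if (any(diff(axis) <= 0)) {
    stop("axis is not strictly monotonic after unit conversion in ", path, call. = FALSE)
  }
  spectrum_tbl(axis, value, domain = domain)
}

#' @rdname read_spectrum
#' @param spectrum Spectrum tibble to write.
#' @param axis_unit Unit to write the axis in ("cm-1" or "nm").
#' @export
write_spectrum <- function(spectrum, path, axis_unit = c("cm-1", "nm")) {
  axis_unit <- match.arg(axis_unit)
  stopifnot(is_spectrum(spectrum))
  axis <- spectrum$wavenumber
  if (axis_unit == "nm") axis <- wavenumber_to_wavelength(axis)
  header <- c(sprintf("# axis: %s", axis_unit),
              sprintf("# domain: %s", attr(spectrum, "domain") %||% "absorbance"))
  rows <- sprintf("%.17g %.17g", axis, spectrum$value)
  writeLines(c(header, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
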