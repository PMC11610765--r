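#' Transient-absorption map
#'
#' Container for a delta-A(delay, wavenumber) matrix with a polarization tag
#' and provenance metadata. Delays are femtoseconds (ascending), the spectral
#' axis is wavenumber in cm^-1 (ascending), delta-A is in mOD.
#'
#' @param delays Ascending delays, fs.
#' @param wavenumber Ascending wavenumber axis, cm^-1.
#' @param dA Matrix `length(delays)` x `length(wavenumber)`, no NaN.
#' @param polarization "parallel", "perpendicular" or "magic".
#' @param meta Named list of metadata (excitation_band, solvent, seed,
#'   fixture_version, ...).
#' @return A `ta_map` object.
#' @export
ta_map <- function(delays, wavenumber, dA,
                   polarization = c("magic", "parallel", "perpendicular"),
                   meta = list()) {
  polarization <- match.arg(polarization)
  delays <- as.numeric(delays)
  wavenumber <- as.numeric(wavenumber)
  dA <- as.matrix(dA)
  if (length(delays) > 1 && any(diff(delays) <= 0)) {
    stop("delays must be strictly ascending", call. = FALSE)
  }
  if (length(wavenumber) > 1 && any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly ascending", call. = FALSE)
  }
  if (!all(dim(dA) == c(length(delays), length(wavenumber)))) {
    stop("dA must be a delays x wavenumber matrix", call. = FALSE)
  }
  if (any(!is.finite(dA))) stop("dA must not contain NaN/Inf", call. = FALSE)
  structure(list(delays = delays, wavenumber = wavenumber, dA = dA,
                 polarization = polarization, meta = meta),
            class = "ta_map")
}

#' @export
print.ta_map <- function(x, ...) {
  cat(sprintf("ta_map: %d delays (%.4g..%.4g fs) x %d wavenumbers (%.5g..%.5g cm-1), %s polarization\n",
              length(x$delays), min(x$delays), max(x$delays),
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$polarization))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v), collapse = ","), ""),
                         sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as_tibble.ta_map <- function(x, ...) {
  tidyr::expand_grid(delay = x$delays, wavenumber = x$wavenumber) |>
    dplyr::mutate(dA = as.vector(t(x$dA)),
                  polarization = x$polarization)
}

#' Extract a spectral slice of a TA map at one delay
#'
#' @param map A [ta_map()].
#' @param delay Requested delay, fs; the nearest stored delay is used.
#' @return Spectrum tibble (domain "delta_A") with attribute `delay`.
#' @export
ta_slice <- function(map, delay) {
  stopifnot(inherits(map, "ta_map"))
  i <- which.min(abs(map$delays - delay))
  out <- spectrum_tbl(map$wavenumber, map$dA[i, ], domain = "delta_A")
  attr(out, "delay") <- map$delays[[i]]
  out
}

#' Average a TA map over a delay window
#'
#' Mean spectrum over all stored delays inside `[from, to]` fs. Useful when
#' the underlying spectra are quasi-static across the window (e.g. the
#' polarization-decomposed lineshape between the end of inter-band transfer
#' and the onset of cooling), where averaging suppresses detector noise
#' without distorting the shape.
#'
#' @param map A [ta_map()].
#' @param from,to Delay window, fs.
#' @return Spectrum tibble (domain "delta_A") with attribute `delay_window`.
#' @export
ta_slice_mean <- function(map, from, to) {
  stopifnot(inherits(map, "ta_map"))
  sel <- map$delays >= from & map$delays <= to
  if (!any(sel)) stop("no delays inside the window", call. = FALSE)
  out <- spectrum_tbl(map$wavenumber, colMeans(map$dA[sel, , drop = FALSE]),
                      domain = "delta_A")
  attr(out, "delay_window") <- c(from, to)
  out
}

#' Read / write TA map containers
#'
#' Self-describing plain-text container: `# key: value` attribute lines
#' (polarization, excitation_band, solvent, seed, fixture_version, ...)
#' followed by `# delays:` and `# wavenumbers:` vectors and the delta-A matrix
#' (one row per delay, full double precision). Round trips are lossless,
#' including attributes.
#'
#' @param map A [ta_map()].
#' @param path File path.
#' @return `read_tamap()` returns a `ta_map`; `write_tamap()` returns `path`
#'   invisibly.
#' @export
write_tamap <- function(map, path) {
  stopifnot(inherits(map, "ta_map"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  hdr <- c("# chladyn_tamap: 1",
           sprintf("# polarization: %s", map$polarization))
  for (nm in names(map$meta)) {
    hdr <- c(hdr, sprintf("# %s: %s", nm, paste(format(map$meta[[nm]], digits = 17),
                                                collapse = " ")))
  }
  hdr <- c(hdr,
           sprintf("# delays: %s", num(map$delays)),
           sprintf("# wavenumbers: %s", num(map$wavenumber)))
  rows <- apply(map$dA, 1, num)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_tamap
#' @export
read_tamap <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  get <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    trimws(sub(sprintf("^#\\s*%s\\s*:\\s*", key), "", m[[1]]))
  }
  if (is.null(get("chladyn_tamap"))) {
    stop("not a chladyn TA map container: ", path, call. = FALSE)
  }
  delays <- as.numeric(strsplit(get("delays") %||% stop("missing delays header"), "\\s+")[[1]])
  wn <- as.numeric(strsplit(get("wavenumbers") %||% stop("missing wavenumbers header"), "\\s+")[[1]])
  if (length(body) != length(delays)) {
    stop("dA block missing or wrong row count in ", path, call. = FALSE)
  }
  dA <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(dA) != length(wn)) stop("dA column count mismatch in ", path, call. = FALSE)
  known <- c("chladyn_tamap", "polarization", "delays", "wavenumbers")
  keys <- sub("^#\\s*([^:]+?)\\s*:.*$", "\\1", hdr)
  meta <- list()
  for (k in setdiff(keys, known)) {
    v <- get(k)
    vn <- suppressWarnings(as.numeric(v))
    meta[[k]] <- if (!is.na(vn)) vn else v
  }
  ta_map(delays, wn, dA, polarization = get("polarization") %||% "magic", meta = meta)
}
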