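#' Construct a spectrum
#'
#' The atom of all spectral arithmetic in the package: a wavelength grid with
#' one intensity per wavelength and a tag saying what kind of signal it holds.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param values Numeric vector, same length: absorbance (AU) or fluorescence
#'   counts (arbitrary units). May be negative (baseline drift) but must be
#'   finite.
#' @param kind One of `"absorbance"`, `"emission"`, `"excitation"`.
#' @param label Free-text label.
#' @return An object of class `spectrum` with fields `wavelengths`, `values`,
#'   `kind`, `label`.
#' @export
#' @examples
#' s <- spectrum(400:500, dnorm(400:500, 450, 20), kind = "emission")
#' range(s$wavelengths)
spectrum <- function(wavelengths, values, kind = c("absorbance", "emission",
                                                   "excitation"),
                     label = "") {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have the same length", call. = FALSE)
  }
  if (length(wavelengths) < 3L) {
    stop("insufficient data: a spectrum needs at least 3 points",
         call. = FALSE)
  }
  if (anyNA(wavelengths) || any(!is.finite(wavelengths))) {
    stop("non-finite wavelength values", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite intensity at index %d (wavelength %g nm)",
                 bad, wavelengths[bad]), call. = FALSE)
  }
  if (anyDuplicated(wavelengths)) {
    dup <- wavelengths[duplicated(wavelengths)][1L]
    stop(sprintf("duplicated wavelength %g nm", dup), call. = FALSE)
  }
  ord <- order(wavelengths)
  structure(list(wavelengths = wavelengths[ord], values = values[ord],
                 kind = kind, label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %g-%g nm%s\n", x$kind,
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

.conc_units <- c("mg/mL", "uM", "M")

#' Construct a titration series
#'
#' Ordered responses indexed by titrant concentration: either one spectrum per
#' concentration or one scalar intensity per concentration. Concentration
#' units are carried explicitly and never converted silently; dissociation
#' constants change unit only through [convert_kd_to_molar()].
#'
#' @param concentrations Non-negative numeric vector; sorted ascending on
#'   construction (entries are reordered with it).
#' @param entries List of [spectrum()] objects or a numeric vector of scalar
#'   intensities, one per concentration.
#' @param unit Concentration unit: `"mg/mL"`, `"uM"` or `"M"`.
#' @param temperature Temperature in K.
#' @param response_label Free text describing the response.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(concentrations, entries, unit = c("mg/mL", "uM",
                                                               "M"),
                             temperature = 298.15, response_label = "") {
  unit <- match.arg(unit)
  concentrations <- as.numeric(concentrations)
  if (anyNA(concentrations) || any(!is.finite(concentrations))) {
    stop("non-finite concentration", call. = FALSE)
  }
  if (any(concentrations < 0)) stop("concentrations must be non-negative",
                                    call. = FALSE)
  if (anyDuplicated(concentrations)) {
    stop("duplicated concentrations in titration series", call. = FALSE)
  }
  scalar <- is.numeric(entries)
  n <- if (scalar) length(entries) else length(entries)
  if (n != length(concentrations)) {
    stop("one entry required per concentration", call. = FALSE)
  }
  if (!scalar && !all(vapply(entries, inherits, logical(1), "spectrum"))) {
    stop("entries must be spectra or a numeric vector", call. = FALSE)
  }
  if (scalar && (anyNA(entries) || any(!is.finite(entries)))) {
    stop("non-finite intensity in titration series", call. = FALSE)
  }
  ord <- order(concentrations)
  entries <- if (scalar) as.numeric(entries)[ord] else entries[ord]
  structure(list(concentrations = concentrations[ord], entries = entries,
                 unit = unit, temperature = temperature,
                 response_label = response_label),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  what <- if (is.numeric(x$entries)) "scalar intensities" else "spectra"
  cat(sprintf("<titration_series> %d %s, %g-%g %s, T = %g K\n",
              length(x$concentrations), what, min(x$concentrations),
              max(x$concentrations), x$unit, x$temperature))
  invisible(x)
}

#' Construct a TCSPC decay histogram
#'
#' @param times Numeric vector of channel times in ns, uniformly spaced
#'   (to 1 ppm).
#' @param counts Non-negative photon counts per channel.
#' @param irf Optional instrument-response counts on the same grid.
#' @param channel_width Channel width in ns; inferred from `times` if omitted.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(times, counts, irf = NULL, channel_width = NULL) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts)) {
    stop("times and counts must have the same length", call. = FALSE)
  }
  if (length(times) < 8L) stop("insufficient channels", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("non-finite counts", call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0)[1L]
    stop(sprintf("negative counts at channel %d", bad), call. = FALSE)
  }
  dt <- diff(times)
  mdt <- stats::median(dt)
  if (mdt <= 0 || any(abs(dt - mdt) > 1e-6 * mdt)) {
    stop("time grid is not uniform to 1 ppm", call. = FALSE)
  }
  if (is.null(channel_width)) channel_width <- mdt
  if (!is.null(irf)) {
    irf <- as.numeric(irf)
    if (length(irf) != length(times)) {
      stop("irf must share the decay time grid", call. = FALSE)
    }
    if (anyNA(irf) || any(!is.finite(irf)) || any(irf < 0)) {
      stop("irf counts must be finite and non-negative", call. = FALSE)
    }
  }
  structure(list(times = times, counts = counts, irf = irf,
                 channel_width = channel_width),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d channels x %g ns, %g total counts%s\n",
              length(x$times), x$channel_width, sum(x$counts),
              if (is.null(x$irf)) "" else ", IRF attached"))
  invisible(x)
}

#' Construct an AFM height map
#'
#' @param heights Numeric matrix of heights in nm.
#' @param pixel_size Pixel edge length in nm.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size = 1) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  if (anyNA(heights) || any(!is.finite(heights))) {
    stop("non-finite heights in map", call. = FALSE)
  }
  if (length(heights) < 4L) stop("height map needs at least 4 pixels",
                                 call. = FALSE)
  structure(list(heights = heights, pixel_size = pixel_size),
            class = "height_map")
}

# --- file readers -----------------------------------------------------------

# Sniff comma vs tab; decimal point only (deterministic parsing).
.read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, sep = sep, header = FALSE,
                    stringsAsFactors = FALSE, strip.white = TRUE,
                    colClasses = "character", comment.char = "#",
                    blank.lines.skip = TRUE)
}

.numeric_or_na <- function(x) suppressWarnings(as.numeric(x))

# Convert character columns, dropping a single leading header row if present.
# Returns list(data = numeric data.frame, header = character or NULL).
.strip_header <- function(raw, path) {
  first_num <- .numeric_or_na(unlist(raw[1L, ], use.names = FALSE))
  if (anyNA(first_num)) {
    header <- as.character(unlist(raw[1L, ], use.names = FALSE))
    raw <- raw[-1L, , drop = FALSE]
  } else {
    header <- NULL
  }
  num <- as.data.frame(lapply(raw, .numeric_or_na))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1L, any))[1L]
    stop(sprintf("parse error in %s: non-numeric value at data row %d",
                 basename(path), bad), call. = FALSE)
  }
  list(data = num, header = header)
}

#' Read a two-column spectrum file
#'
#' Expects a CSV or TSV with wavelength in the first column and intensity in
#' the second; a single header row is allowed and ignored.
#'
#' @param path File path.
#' @param kind Spectrum kind passed to [spectrum()].
#' @param label Optional label; defaults to the file name.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("absorbance", "emission",
                                         "excitation"), label = NULL) {
  kind <- match.arg(kind)
  parsed <- .strip_header(.read_table_auto(path), path)
  d <- parsed$data
  if (ncol(d) < 2L) stop("spectrum file needs two columns", call. = FALSE)
  spectrum(d[[1L]], d[[2L]], kind = kind,
           label = if (is.null(label)) basename(path) else label)
}

#' Write a spectrum to CSV
#'
#' Values are written at full double precision so that
#' `read_spectrum(write_spectrum(s))` round-trips to 1e-12 relative.
#'
#' @param x A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  lines <- c("wavelength_nm,value",
             paste(format(x$wavelengths, digits = 17, trim = TRUE),
                   format(x$values, digits = 17, trim = TRUE), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a titration series from file
#'
#' Two dialects are accepted. Wide: the first column is wavelength and each
#' remaining column is one spectrum, with the titrant concentration in the
#' header row. Long: three columns (concentration, wavelength, value), header
#' optional. Both parse to the same `titration_series`, sorted ascending by
#' concentration.
#'
#' @param path File path.
#' @param unit Concentration unit (`"mg/mL"`, `"uM"`, `"M"`); required,
#'   never inferred.
#' @param kind Spectrum kind for the entries.
#' @param temperature Temperature in K recorded on the series.
#' @return A [titration_series()] of spectra.
#' @export
read_titration <- function(path, unit, kind = c("absorbance", "emission",
                                                "excitation"),
                           temperature = 298.15) {
  kind <- match.arg(kind)
  unit <- match.arg(unit, .conc_units)
  raw <- .read_table_auto(path)
  first <- as.character(unlist(raw[1L, ], use.names = FALSE))
  first_num <- .numeric_or_na(first)
  # Dialect detection: a wide file carries a header row whose first cell is a
  # wavelength label (non-numeric) and whose remaining cells are the titrant
  # concentrations. Anything else with exactly 3 columns is the long dialect
  # (concentration, wavelength, value).
  wide <- is.na(first_num[1L]) && length(first_num) > 1L &&
    !anyNA(first_num[-1L])
  if (!wide) {
    if (ncol(raw) != 3L) {
      stop(sprintf("missing concentration header in %s", basename(path)),
           call. = FALSE)
    }
    parsed <- .strip_header(raw, path)
    d <- parsed$data
    names(d) <- c("concentration", "wavelength", "value")
    concs <- sort(unique(d$concentration))
    entries <- lapply(concs, function(cc) {
      sub <- d[d$concentration == cc, , drop = FALSE]
      spectrum(sub$wavelength, sub$value, kind = kind,
               label = sprintf("c=%g", cc))
    })
    return(titration_series(concs, entries, unit = unit,
                            temperature = temperature))
  }
  concs <- first_num[-1L]
  parsed <- .strip_header(raw, path)
  d <- parsed$data
  entries <- lapply(seq_along(concs), function(j) {
    spectrum(d[[1L]], d[[j + 1L]], kind = kind,
             label = sprintf("c=%g", concs[j]))
  })
  titration_series(concs, entries, unit = unit, temperature = temperature)
}

#' Write a titration series of spectra in the wide dialect
#'
#' First column wavelength, one column per concentration with the
#' concentration in the header. Full double precision, so read/write
#' round-trips are exact to 1e-12 relative.
#'
#' @param x A [titration_series()] of spectra on a common grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(x, path) {
  stopifnot(inherits(x, "titration_series"))
  if (is.numeric(x$entries)) {
    stop("write_titration expects a series of spectra", call. = FALSE)
  }
  grid <- x$entries[[1L]]$wavelengths
  mat <- vapply(x$entries, function(s) s$values, numeric(length(grid)))
  header <- paste(c("wavelength_nm",
                    format(x$concentrations, digits = 17, trim = TRUE)),
                  collapse = ",")
  rows <- apply(cbind(grid, mat), 1L, function(r) {
    paste(format(r, digits = 17, trim = TRUE), collapse = ",")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a TCSPC decay histogram to CSV
#'
#' @param x A [decay_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay <- function(x, path) {
  stopifnot(inherits(x, "decay_histogram"))
  cols <- cbind(x$times, x$counts)
  header <- "time_ns,counts"
  if (!is.null(x$irf)) {
    cols <- cbind(cols, x$irf)
    header <- "time_ns,counts,irf"
  }
  rows <- apply(cols, 1L, function(r) {
    paste(format(r, digits = 17, trim = TRUE), collapse = ",")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write an AFM height map as a CSV grid
#'
#' @param x A [height_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(x, path) {
  stopifnot(inherits(x, "height_map"))
  rows <- apply(x$heights, 1L, function(r) {
    paste(format(r, digits = 17, trim = TRUE), collapse = ",")
  })
  writeLines(rows, path)
  invisible(path)
}

#' Read a TCSPC decay histogram
#'
#' Expects columns time (ns), counts, and optionally IRF counts; a header row
#' is allowed. The time grid must be uniform to 1 ppm and counts non-negative.
#'
#' @param path File path.
#' @return A [decay_histogram()] with `channel_width` inferred from the grid.
#' @export
read_decay <- function(path) {
  parsed <- .strip_header(.read_table_auto(path), path)
  d <- parsed$data
  if (ncol(d) < 2L) stop("decay file needs time and counts columns",
                         call. = FALSE)
  irf <- if (ncol(d) >= 3L) d[[3L]] else NULL
  decay_histogram(d[[1L]], d[[2L]], irf = irf)
}

#' Read an AFM height map stored as a CSV grid
#'
#' @param path File path; rectangular numeric grid, no header.
#' @param pixel_size Pixel edge length in nm.
#' @return A [height_map()].
#' @export
read_height_map <- function(path, pixel_size = 1) {
  parsed <- .strip_header(.read_table_auto(path), path)
  height_map(as.matrix(parsed$data), pixel_size = pixel_size)
}
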