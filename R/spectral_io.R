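#' Supported measurement modalities
#'
#' Four optical channels are produced by the instrument: UV/Vis transmission
#' (`uvvis`), fluorescence under 440 nm excitation (`fl440`), fluorescence
#' under 590 nm excitation (`fl590`), and scattered light under 850 nm
#' excitation (`sc850`).
#'
#' @format Character vector of length four.
#' @export
MODALITIES <- c("uvvis", "fl440", "fl590", "sc850")

# Detector ceiling in raw counts; the system clips near this value.
DEFAULT_SATURATION_COUNTS <- 40000

#' Uniform wavelength grid
#'
#' The spectrometer samples 225-900 nm at 1.5 nm resolution; that range is
#' the default. All downstream computation runs on a common grid, so inputs
#' on other grids are resampled first (see [resample()]).
#'
#' @param start_nm First wavelength in nm.
#' @param stop_nm Last wavelength in nm (must exceed `start_nm`).
#' @param step_nm Grid spacing in nm (positive).
#' @return An object of class `wavelength_grid`.
#' @export
#' @examples
#' g <- wavelength_grid()
#' length(wavelengths(g))
wavelength_grid <- function(start_nm = 225, stop_nm = 900, step_nm = 1.5) {
  if (!(start_nm < stop_nm)) stop("start_nm must be below stop_nm")
  if (!(step_nm > 0)) stop("step_nm must be positive")
  structure(list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm),
            class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @return `wavelengths()` returns the numeric vector of grid points in nm.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  seq(grid$start_nm, grid$stop_nm, by = grid$step_nm)
}

#' Construct a spectrum
#'
#' A spectrum couples a strictly increasing wavelength axis (nm) with
#' detector intensities (counts) for one modality. The `saturated` flag is
#' derived from the configured ceiling, defaulting to the system limit of
#' 40,000 counts.
#'
#' @param values Numeric intensities, one per wavelength; must be finite.
#' @param wavelength Numeric wavelengths in nm, or a [wavelength_grid()].
#' @param modality One of [MODALITIES].
#' @param temperature_c Acquisition temperature in deg C (optional).
#' @param is_blank Logical; `TRUE` for a pure-water blank.
#' @param saturation_limit Counts at or above which the detector saturates.
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(values, wavelength, modality,
                         temperature_c = NA_real_, is_blank = FALSE,
                         saturation_limit = DEFAULT_SATURATION_COUNTS) {
  if (inherits(wavelength, "wavelength_grid")) wavelength <- wavelengths(wavelength)
  modality <- match.arg(modality, MODALITIES)
  values <- as.numeric(values)
  wavelength <- as.numeric(wavelength)
  if (length(values) != length(wavelength))
    stop("values and wavelength differ in length")
  if (!all(is.finite(values))) stop("spectrum values must be finite")
  if (length(wavelength) < 2L || is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(list(
    wavelength = wavelength,
    values = values,
    modality = modality,
    temperature_c = as.numeric(temperature_c),
    is_blank = isTRUE(is_blank),
    saturated = any(values >= saturation_limit),
    saturation_limit = saturation_limit,
    flags = character(),
    provenance = character()
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.1f-%.1f nm%s%s\n",
              x$modality, length(x$values),
              min(x$wavelength), max(x$wavelength),
              if (x$is_blank) ", blank" else "",
              if (x$saturated) ", SATURATED" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

add_flag <- function(spec, flag) {
  spec$flags <- union(spec$flags, flag)
  spec
}

add_provenance <- function(spec, step) {
  spec$provenance <- c(spec$provenance, step)
  spec
}

#' Write / read a spectrum in the package CSV dialect
#'
#' Files are plain CSV with self-describing header lines
#' (`# modality=`, `# temperature_c=`, `# is_blank=`, optional
#' `# provenance=`), then a `wavelength_nm,intensity_counts` table. The
#' round trip preserves values to full double precision.
#'
#' @param spec A `spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modality=%s", spec$modality), con)
  writeLines(sprintf("# temperature_c=%s",
                     formatC(spec$temperature_c, digits = 17, format = "g")), con)
  writeLines(sprintf("# is_blank=%s", if (spec$is_blank) "true" else "false"), con)
  for (p in spec$provenance) writeLines(sprintf("# provenance=%s", p), con)
  writeLines("wavelength_nm,intensity_counts", con)
  writeLines(sprintf("%s,%s",
                     formatC(spec$wavelength, digits = 17, format = "g"),
                     formatC(spec$values, digits = 17, format = "g")), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @param modality Expected modality; overrides the file header when given.
#' @param saturation_limit Ceiling used to derive the `saturated` flag.
#' @return `read_spectrum()` returns a `spectrum` on its native grid.
#' @export
read_spectrum <- function(path, modality = NULL,
                          saturation_limit = DEFAULT_SATURATION_COUNTS) {
  if (!file.exists(path)) stop(sprintf("spectrum file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("empty spectrum file: %s", path))
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  body <- lines[!hdr]
  get_meta <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), meta, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(sprintf("^#\\s*%s=", key), "", hit[1])
  }
  file_modality <- get_meta("modality")
  if (is.null(modality)) modality <- file_modality
  if (is.na(modality) || !modality %in% MODALITIES)
    stop(sprintf("spectrum file %s: missing or unknown modality header", path))
  if (!length(body) || !identical(trimws(body[1]), "wavelength_nm,intensity_counts"))
    stop(sprintf("spectrum file %s: expected column header 'wavelength_nm,intensity_counts' at line %d",
                 path, sum(hdr) + 1L))
  rows <- body[-1]
  if (!length(rows)) stop(sprintf("spectrum file %s: no data rows", path))
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop(sprintf("spectrum file %s: malformed row at line %d",
                 path, sum(hdr) + 1L + bad[1]))
  wl <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  iv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  nn <- which(!is.finite(wl) | !is.finite(iv))
  if (length(nn))
    stop(sprintf("spectrum file %s: non-numeric value at line %d",
                 path, sum(hdr) + 1L + nn[1]))
  mono_bad <- which(diff(wl) <= 0)
  if (length(mono_bad))
    stop(sprintf("spectrum file %s: wavelengths not strictly increasing at line %d",
                 path, sum(hdr) + 2L + mono_bad[1]))
  temp <- suppressWarnings(as.numeric(get_meta("temperature_c")))
  spec <- new_spectrum(iv, wl, modality,
                       temperature_c = temp,
                       is_blank = identical(get_meta("is_blank"), "true"),
                       saturation_limit = saturation_limit)
  prov <- grep("^#\\s*provenance=", meta, value = TRUE)
  spec$provenance <- sub("^#\\s*provenance=", "", prov)
  spec
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation onto the target wavelengths. The target grid must
#' lie within the source span; extrapolation is refused. Modality, flags
#' and metadata are preserved.
#'
#' @param spec A `spectrum`.
#' @param grid A [wavelength_grid()] or numeric wavelength vector.
#' @return A `spectrum` on the target grid.
#' @export
resample <- function(spec, grid) {
  stopifnot(inherits(spec, "spectrum"))
  wl_to <- if (inherits(grid, "wavelength_grid")) wavelengths(grid) else as.numeric(grid)
  if (min(wl_to) < min(spec$wavelength) - 1e-9 ||
      max(wl_to) > max(spec$wavelength) + 1e-9)
    stop("target grid extends beyond the source wavelength span (extrapolation refused)")
  vals <- stats::approx(spec$wavelength, spec$values, xout = wl_to, rule = 1)$y
  out <- spec
  out$wavelength <- wl_to
  out$values <- vals
  out <- add_provenance(out, sprintf("resample[%g-%g nm]", min(wl_to), max(wl_to)))
  out
}

#' Bundle the spectra of one sample
#'
#' A measurement bundle holds, for one sample, the sample spectrum and the
#' matching pure-water blank for each available modality.
#'
#' @param sample_id Identifier string.
#' @param spectra Named list of `spectrum` objects, names in [MODALITIES].
#' @param blanks Named list of blank `spectrum` objects, same convention.
#' @return An object of class `measurement_bundle`.
#' @export
measurement_bundle <- function(sample_id, spectra, blanks) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  check_named <- function(lst, what) {
    if (length(lst) && (is.null(names(lst)) || !all(names(lst) %in% MODALITIES)))
      stop(sprintf("%s must be a list named by modality", what))
    for (s in lst) stopifnot(inherits(s, "spectrum"))
    lst
  }
  structure(list(sample_id = sample_id,
                 spectra = check_named(spectra, "spectra"),
                 blanks = check_named(blanks, "blanks")),
            class = "measurement_bundle")
}

#' Validate a measurement bundle
#'
#' Report-only check: lists missing blanks (fatal), wavelength-grid
#' mismatches between sample and blank (fatal), and saturation (warning,
#' non-fatal). `ok` is `TRUE` iff no fatal issue was found.
#'
#' @param bundle A [measurement_bundle()].
#' @return List with `ok` (logical) and `issues` (data frame with columns
#'   `modality`, `issue`, `fatal`).
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "measurement_bundle"))
  issues <- data.frame(modality = character(), issue = character(),
                       fatal = logical(), stringsAsFactors = FALSE)
  note <- function(modality, issue, fatal) {
    issues[nrow(issues) + 1L, ] <<- list(modality, issue, fatal)
  }
  for (m in names(bundle$spectra)) {
    s <- bundle$spectra[[m]]
    b <- bundle$blanks[[m]]
    if (is.null(b)) {
      note(m, "missing blank", TRUE)
    } else if (length(b$wavelength) != length(s$wavelength) ||
               any(abs(b$wavelength - s$wavelength) > 1e-9)) {
      note(m, "blank and sample on different wavelength grids", TRUE)
    }
    if (s$saturated) note(m, "sample spectrum saturated", FALSE)
    if (!is.null(b) && b$saturated) note(m, "blank spectrum saturated", FALSE)
  }
  list(ok = !any(issues$fatal), issues = issues)
}
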