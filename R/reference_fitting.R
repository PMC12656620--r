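#' Evaluate a sum of Gaussian components
#'
#' Components use the denominator width convention
#' `a * exp(-(lambda - center)^2 / width)` with `width` in nm^2.
#'
#' @param wavelength Wavelengths in nm.
#' @param components Data frame with columns `amplitude`, `center`, `width`.
#' @return Numeric vector, the component sum at each wavelength.
#' @export
eval_components <- function(wavelength, components) {
  if (!nrow(components)) return(numeric(length(wavelength)))
  out <- numeric(length(wavelength))
  for (i in seq_len(nrow(components))) {
    out <- out + components$amplitude[i] *
      exp(-(wavelength - components$center[i])^2 / components$width[i])
  }
  out
}

#' Reference spectrum as a scaled Gaussian sum
#'
#' A reference spectrum describes one substance in one modality as a sum of
#' Gaussian bands. The per-sample intensity scale `k` is not stored here;
#' it is fitted at scoring time (see [score_against_reference()]).
#'
#' @param substance Substance label.
#' @param modality One of [MODALITIES].
#' @param components Data frame with columns `amplitude` (> 0), `center`
#'   (nm), `width` (nm^2, > 0); at least one row.
#' @return Object of class `reference_spectrum`.
#' @export
reference_spectrum <- function(substance, modality, components) {
  modality <- match.arg(modality, MODALITIES)
  components <- as.data.frame(components)
  stopifnot(all(c("amplitude", "center", "width") %in% names(components)))
  if (!nrow(components)) stop("reference needs at least one Gaussian component")
  if (any(components$amplitude <= 0) || any(components$width <= 0))
    stop("component amplitudes and widths must be positive")
  structure(list(substance = substance, modality = modality,
                 components = components[, c("amplitude", "center", "width")]),
            class = "reference_spectrum")
}

#' @export
print.reference_spectrum <- function(x, ...) {
  cat(sprintf("<reference_spectrum> %s / %s: %d Gaussian component(s)\n",
              x$substance, x$modality, nrow(x$components)))
  invisible(x)
}

spectrum_signal <- function(x) {
  if (inherits(x, "spectrum")) list(wl = x$wavelength, y = x$values)
  else if (inherits(x, "absorbance_spectrum")) list(wl = x$wavelength, y = x$absorbance)
  else if (is.list(x) && !is.null(x$wl) && !is.null(x$y)) x
  else stop("expected a spectrum or absorbance_spectrum")
}

# Robust noise scale from first differences (white noise: sd(diff) = sd*sqrt(2)).
estimate_noise_mad <- function(y) stats::mad(diff(y)) / sqrt(2)

#' Locate significant peaks in a processed spectrum
#'
#' Local maxima whose prominence over the adjacent valleys exceeds a
#' threshold, sorted by height descending. The default threshold is five
#' times the noise scale estimated from first differences, so pure noise
#' yields no peaks while real bands in this instrument regime sit far
#' above it.
#'
#' @param x A processed `spectrum`/`absorbance_spectrum`.
#' @param min_prominence Absolute prominence threshold; `NULL` for the
#'   noise-derived default.
#' @param noise_factor Multiplier on the noise scale for the default
#'   threshold.
#' @return Data frame with columns `center` (nm), `height`, `prominence`,
#'   `index`; zero rows when nothing is significant.
#' @export
find_significant_peaks <- function(x, min_prominence = NULL, noise_factor = 5) {
  sig <- spectrum_signal(x)
  y <- sig$y
  n <- length(y)
  empty <- data.frame(center = numeric(), height = numeric(),
                      prominence = numeric(), index = integer())
  if (n < 3L) return(empty)
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_peak)) return(empty)
  if (is.null(min_prominence))
    min_prominence <- noise_factor * estimate_noise_mad(y)
  prom <- vapply(is_peak, function(i) {
    # walk outward until terrain rises above the peak; valley = min en route
    lseg <- y[(i - 1L):1]
    rise_l <- which(lseg > y[i])
    lmin <- min(lseg[seq_len(if (length(rise_l)) rise_l[1] - 1L else length(lseg))])
    rseg <- y[(i + 1L):n]
    rise_r <- which(rseg > y[i])
    rmin <- min(rseg[seq_len(if (length(rise_r)) rise_r[1] - 1L else length(rseg))])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence & is.finite(prom)
  if (!any(keep)) return(empty)
  out <- data.frame(center = sig$wl[is_peak[keep]],
                    height = y[is_peak[keep]],
                    prominence = prom[keep],
                    index = is_peak[keep])
  out[order(-out$height), , drop = FALSE]
}

# Fit one Gaussian to the neighbourhood of a detected peak; returns a
# one-row component data frame, or NULL when the fit fails.
fit_one_gaussian <- function(wl, y, peak_index, window_sigmas = 3) {
  n <- length(y)
  h <- y[peak_index]
  half <- h / 2
  right <- peak_index
  while (right < n && y[right] > half) right <- right + 1L
  left <- peak_index
  while (left > 1L && y[left] > half) left <- left - 1L
  fwhm <- max(wl[right] - wl[left], 2 * (wl[2] - wl[1]))
  sigma <- fwhm / 2.3548
  c0 <- 2 * sigma^2                     # denominator-form width, nm^2
  win <- which(abs(wl - wl[peak_index]) <= window_sigmas * sigma)
  if (length(win) < 5L) win <- max(1L, peak_index - 4L):min(n, peak_index + 4L)
  df <- data.frame(w = wl[win], v = y[win])
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a * exp(-(w - l0)^2 / cc), data = df,
                      start = list(a = h, l0 = wl[peak_index], cc = c0),
                      lower = c(a = 0, l0 = min(wl), cc = (wl[2] - wl[1])^2 / 4),
                      upper = c(a = Inf, l0 = max(wl), cc = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (p[["a"]] <= 0 || !is.finite(p[["a"]])) return(NULL)
  data.frame(amplitude = p[["a"]], center = p[["l0"]], width = p[["cc"]])
}

#' Build a Gaussian-sum reference spectrum by iterative peak fitting
#'
#' Repeatedly fits the tallest remaining significant peak with a Gaussian
#' (least squares within a +/- 3 sigma window) and subtracts it from the
#' residual, until the residual is almost flat (maximum below
#' `flatness_frac` of the original maximum) or no peak passes the
#' prominence rule. Residual RMS is non-increasing across iterations; an
#' iteration that fails to decrease it is rejected and terminates the loop.
#'
#' @param x Processed `spectrum` or `absorbance_spectrum` with at least one
#'   significant peak.
#' @param substance Label stored on the reference.
#' @param flatness_frac Stop when the residual max falls below this
#'   fraction of the original spectrum max.
#' @param max_components Safety cap on the number of Gaussians.
#' @param min_prominence Passed to [find_significant_peaks()].
#' @return A [reference_spectrum()].
#' @export
build_reference <- function(x, substance = "unknown", flatness_frac = 0.02,
                            max_components = 12, min_prominence = NULL) {
  sig <- spectrum_signal(x)
  modality <- if (inherits(x, "absorbance_spectrum")) "uvvis" else x$modality
  wl <- sig$wl
  resid <- sig$y
  orig_max <- max(resid)
  if (!is.finite(orig_max) || orig_max <= 0)
    stop("no significant peaks: cannot build an empty reference")
  comps <- data.frame(amplitude = numeric(), center = numeric(), width = numeric())
  rms <- sqrt(mean(resid^2))
  for (iter in seq_len(max_components)) {
    peaks <- find_significant_peaks(list(wl = wl, y = resid),
                                    min_prominence = min_prominence)
    peaks <- peaks[peaks$height >= flatness_frac * orig_max, , drop = FALSE]
    if (!nrow(peaks)) break
    comp <- fit_one_gaussian(wl, resid, peaks$index[1])
    if (is.null(comp)) break
    new_resid <- resid - eval_components(wl, comp)
    new_rms <- sqrt(mean(new_resid^2))
    if (new_rms >= rms) break                      # monotone-descent guard
    resid <- new_resid
    rms <- new_rms
    comps <- rbind(comps, comp)
    if (max(resid) < flatness_frac * orig_max) break
  }
  if (!nrow(comps))
    stop("no significant peaks: cannot build an empty reference")
  reference_spectrum(substance, modality, comps)
}

#' Score a spectrum against a reference
#'
#' Fits the intensity scale `k` of the reference to the spectrum by
#' closed-form least squares and reports the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` over the full wavelength grid. A poor fit
#' (negative raw value) is floored to zero, the convention used for the
#' classification features.
#'
#' @param x Processed `spectrum` or `absorbance_spectrum`.
#' @param ref A [reference_spectrum()].
#' @return List of class `fit_result`: `k`, `r_squared`, `residual_rms`.
#' @export
score_against_reference <- function(x, ref) {
  stopifnot(inherits(ref, "reference_spectrum"))
  sig <- spectrum_signal(x)
  rv <- eval_components(sig$wl, ref$components)
  denom <- sum(rv^2)
  if (denom <= 0) stop("degenerate reference: evaluates to zero on this grid")
  k <- sum(sig$y * rv) / denom
  res <- sig$y - k * rv
  ss_tot <- sum((sig$y - mean(sig$y))^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - sum(res^2) / ss_tot
  structure(list(k = k,
                 r_squared = min(1, max(0, r2)),
                 residual_rms = sqrt(mean(res^2))),
            class = "fit_result")
}

#' Default designated reference assignments
#'
#' Each feature column is the conformity of one modality against one
#' designated substance reference: the chlorophyll-band references (from
#' spinach extract) for `uvvis` and `fl440`, the phycocyanin reference for
#' `fl590`, and the turbidity-standard scatter reference for `sc850`.
#'
#' @return Named character vector mapping modality to substance label.
#' @export
default_designations <- function() {
  c(uvvis = "spinach", fl440 = "spinach",
    fl590 = "phycocyanin", sc850 = "turbidity_standard")
}

library_key <- function(substance, modality) paste(substance, modality, sep = "/")

#' Extract the per-modality conformity feature vector for one bundle
#'
#' For each modality the preprocessed signal is scored against its
#' designated reference; absent or failed modalities are recorded as 0
#' (the poor-fit convention). The turbidity estimate is carried along,
#' normalized by the compensation validity bound, as the `turb` feature.
#'
#' @param prep Output of [preprocess_bundle()].
#' @param ref_library Named list of [reference_spectrum()] objects keyed
#'   `"substance/modality"` (see [build_reference_library()]).
#' @param designations Modality-to-substance map, see
#'   [default_designations()].
#' @param valid_max_fnu Normalization constant for the `turb` feature.
#' @return One-row data frame: `sample_id`, `r2_440`, `r2_590`, `r2_850`,
#'   `r2_uvvis`, `turb`.
#' @export
extract_features <- function(prep, ref_library,
                             designations = default_designations(),
                             valid_max_fnu = 20) {
  if (!length(ref_library)) stop("empty reference library")
  score_or_zero <- function(obj, modality) {
    if (is.null(obj)) return(0)
    key <- library_key(designations[[modality]], modality)
    ref <- ref_library[[key]]
    if (is.null(ref)) stop(sprintf("reference library lacks entry %s", key))
    tryCatch(score_against_reference(obj, ref)$r_squared, error = function(e) 0)
  }
  data.frame(
    sample_id = prep$sample_id,
    r2_440 = score_or_zero(prep$emission$fl440, "fl440"),
    r2_590 = score_or_zero(prep$emission$fl590, "fl590"),
    r2_850 = score_or_zero(prep$emission$sc850, "sc850"),
    r2_uvvis = score_or_zero(prep$absorbance, "uvvis"),
    turb = if (is.na(prep$fnu)) 0 else prep$fnu / valid_max_fnu,
    stringsAsFactors = FALSE)
}

#' Serialize / load a reference library
#'
#' The library is stored as JSON: one record per reference with substance,
#' modality and the Gaussian component table.
#'
#' @param ref_library Named list of [reference_spectrum()] objects.
#' @param path JSON file path.
#' @export
save_reference_library <- function(ref_library, path) {
  recs <- lapply(ref_library, function(r)
    list(substance = r$substance, modality = r$modality,
         components = r$components))
  jsonlite::write_json(recs, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_reference_library
#' @return `load_reference_library()` returns the named list of references.
#' @export
load_reference_library <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(recs, function(r)
    reference_spectrum(r$substance, r$modality, as.data.frame(r$components)))
  names(out) <- vapply(out, function(r) library_key(r$substance, r$modality), "")
  out
}
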