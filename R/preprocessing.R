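#' Low-pass FIR filter specification
#'
#' The smoothing filter is a 30th-order (31-tap) linear-phase FIR low-pass
#' with passband edge at 0.1 and stopband edge at 0.3 of the sampling rate,
#' applied bidirectionally so the net phase response is zero.
#'
#' @param order Filter order (taps minus one); even and >= 2.
#' @param passband_frac Passband edge as a fraction of the sampling rate.
#' @param stopband_frac Stopband edge as a fraction of the sampling rate.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(order = 30, passband_frac = 0.1, stopband_frac = 0.3) {
  if (order < 2 || order %% 2 != 0) stop("filter order must be even and >= 2")
  if (!(passband_frac > 0 && passband_frac < stopband_frac && stopband_frac < 0.5))
    stop("need 0 < passband_frac < stopband_frac < 0.5")
  structure(list(order = order, passband_frac = passband_frac,
                 stopband_frac = stopband_frac), class = "filter_spec")
}

#' Design the low-pass filter taps
#'
#' Windowed-sinc (Hamming) design with the cutoff midway between the
#' passband and stopband edges. Taps are normalized to unit DC gain and are
#' symmetric (linear phase).
#'
#' @param spec A [filter_spec()].
#' @return Numeric vector of `order + 1` taps summing to one.
#' @export
design_lowpass <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  cutoff_fs <- (spec$passband_frac + spec$stopband_frac) / 2  # fraction of fs
  # signal::fir1 takes the cutoff relative to Nyquist (fs/2)
  taps <- signal::fir1(spec$order, 2 * cutoff_fs, type = "low",
                       window = signal::hamming(spec$order + 1))
  taps <- as.numeric(taps)
  taps / sum(taps)
}

# Single causal FIR pass (convolution); y[i] = sum_j h[j] x[i-j+1].
fir_pass <- function(x, h) {
  stats::convolve(x, rev(h), type = "open")[seq_along(x)]
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the FIR taps forward and then backward so peak positions are
#' preserved exactly and the effective magnitude response is the squared
#' single-pass magnitude. Edges are handled by odd-symmetric signal
#' extension of three filter lengths on each side.
#'
#' @param x A `spectrum`, or a bare numeric vector.
#' @param taps Filter coefficients from [design_lowpass()].
#' @return Filtered object of the same type as `x`.
#' @export
zero_phase_filter <- function(x, taps = design_lowpass()) {
  if (inherits(x, "spectrum")) {
    out <- x
    out$values <- zero_phase_filter(x$values, taps)
    return(add_provenance(out, "zero_phase_filter"))
  }
  if (inherits(x, "absorbance_spectrum")) {
    out <- x
    out$absorbance <- zero_phase_filter(x$absorbance, taps)
    out$provenance <- c(out$provenance, "zero_phase_filter")
    return(out)
  }
  n <- length(x)
  L <- length(taps)
  if (n <= 3L * L) stop("spectrum too short for zero-phase filtering (need > 3 filter lengths)")
  next_ <- 3L * L
  left <- 2 * x[1] - x[(next_ + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - next_)]
  xp <- c(left, x, right)
  yp <- fir_pass(xp, taps)
  yp <- rev(fir_pass(rev(yp), taps))
  yp[(next_ + 1L):(next_ + n)]
}

#' Convert a UV/Vis sample and blank to absorbance
#'
#' Beer-Lambert conversion `A(lambda) = log10(I0 / I)` with the pure-water
#' blank as the incident intensity `I0`. Sample intensities at or below
#' zero are clipped to `epsilon` before the ratio and the result is flagged.
#'
#' @param sample `spectrum` with modality `uvvis`.
#' @param blank Matching blank `spectrum` (same grid, strictly positive).
#' @param epsilon Clip floor for non-positive sample counts.
#' @return Object of class `absorbance_spectrum` with fields `wavelength`,
#'   `absorbance`, `flags`, `provenance`.
#' @export
compute_absorbance <- function(sample, blank, epsilon = 1e-3) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (sample$modality != "uvvis" || blank$modality != "uvvis")
    stop("compute_absorbance expects uvvis spectra")
  check_same_grid(sample, blank)
  if (any(blank$values <= 0))
    stop("blank contains non-positive intensities: calibration error")
  iv <- sample$values
  flags <- character()
  if (any(iv <= 0)) {
    iv <- pmax(iv, epsilon)
    flags <- "clipped_nonpositive_sample"
  }
  structure(list(wavelength = sample$wavelength,
                 absorbance = log10(blank$values / iv),
                 flags = flags,
                 temperature_c = sample$temperature_c,
                 provenance = c(sample$provenance, "compute_absorbance")),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> %d points, max A = %.4f\n",
              length(x$absorbance), max(x$absorbance)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (length(a$wavelength) != length(b$wavelength) ||
      any(abs(a$wavelength - b$wavelength) > 1e-9))
    stop("spectra are on different wavelength grids")
  invisible(TRUE)
}

#' Blank subtraction for emission-type spectra
#'
#' For fluorescence and scattered-light channels the blank is subtracted:
#' `F(lambda) = I(lambda) - I0(lambda)`. Negative values are preserved (they
#' carry information for later filtering and baseline correction); if any
#' occur the result is flagged `negative_values`.
#'
#' @param sample `spectrum` with modality `fl440`, `fl590` or `sc850`.
#' @param blank Blank `spectrum` of the same modality on the same grid.
#' @return Blank-subtracted `spectrum`.
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (sample$modality == "uvvis")
    stop("subtract_blank is for fl440/fl590/sc850; use compute_absorbance for uvvis")
  if (sample$modality != blank$modality)
    stop(sprintf("modality mismatch: sample %s vs blank %s",
                 sample$modality, blank$modality))
  check_same_grid(sample, blank)
  out <- sample
  out$values <- sample$values - blank$values
  out$is_blank <- FALSE
  if (any(out$values < 0)) out <- add_flag(out, "negative_values")
  add_provenance(out, "subtract_blank")
}

#' Optional baseline-offset correction
#'
#' Field spectra can show a slight systematic negative shift after blank
#' subtraction. When the 5th percentile of the values is negative beyond
#' what zero-mean noise explains (below `-noise_sigmas` times the noise
#' scale estimated from first differences), it is subtracted, lifting the
#' baseline to approximately zero; otherwise the spectrum is returned
#' unchanged. The significance gate matters: the 5th percentile of pure
#' noise is itself negative, and correcting it would bias every weak
#' spectrum upward.
#'
#' @param spec A blank-subtracted `spectrum`.
#' @param noise_sigmas Trigger threshold in noise standard deviations.
#' @return Corrected `spectrum`.
#' @export
correct_baseline <- function(spec, noise_sigmas = 3) {
  stopifnot(inherits(spec, "spectrum"))
  q <- stats::quantile(spec$values, 0.05, names = FALSE)
  noise <- estimate_noise_mad(spec$values)
  if (q < -noise_sigmas * noise) {
    spec$values <- spec$values - q
    spec <- add_provenance(spec, sprintf("baseline_offset[%+.4g]", -q))
  }
  spec
}

#' Temperature-correction model
#'
#' The instrument response drifts with temperature; spectra are normalized
#' to a reference temperature of 21.3 deg C with a multiplicative,
#' light-source-specific factor. The raw response is modelled as
#' `1 + slope * (T - 21.3)` per modality, so the correction factor is its
#' reciprocal (exactly 1 at the reference temperature). The model is valid
#' up to about 30 deg C; above that the correction is still applied but the
#' result is flagged, since non-linear thermal effects may dominate.
#'
#' @param reference_temp_c Reference temperature, deg C.
#' @param slopes Named numeric, per-modality relative drift per deg C.
#' @param valid_max_c Upper validity bound, deg C.
#' @return Object of class `temperature_model`.
#' @export
temperature_model <- function(reference_temp_c = 21.3,
                              slopes = c(uvvis = 0.004, fl440 = 0.008,
                                         fl590 = 0.007, sc850 = 0.010),
                              valid_max_c = 30) {
  stopifnot(all(MODALITIES %in% names(slopes)))
  structure(list(reference_temp_c = reference_temp_c,
                 slopes = slopes[MODALITIES],
                 valid_max_c = valid_max_c),
            class = "temperature_model")
}

# Relative instrument response at temperature T for a modality (1 at ref).
temperature_response <- function(model, modality, temperature_c) {
  1 + model$slopes[[modality]] * (temperature_c - model$reference_temp_c)
}

#' Normalize a spectrum to the reference temperature
#'
#' Multiplies the values by the modality-specific correction factor
#' `1 / (1 + slope * (T - T_ref))`. Requires the acquisition temperature to
#' be recorded on the spectrum. Above the validity bound a
#' `temperature_out_of_range` flag is attached (correction still applied).
#'
#' @param x A `spectrum` or `absorbance_spectrum` (the latter uses the
#'   `uvvis` slope).
#' @param model A [temperature_model()].
#' @return Corrected object of the same class.
#' @export
temperature_correct <- function(x, model = temperature_model()) {
  stopifnot(inherits(model, "temperature_model"))
  temp <- x$temperature_c
  if (is.null(temp) || !length(temp) || is.na(temp))
    stop("spectrum carries no acquisition temperature")
  modality <- if (inherits(x, "absorbance_spectrum")) "uvvis" else x$modality
  f <- 1 / temperature_response(model, modality, temp)
  if (inherits(x, "absorbance_spectrum")) {
    x$absorbance <- x$absorbance * f
  } else {
    x$values <- x$values * f
  }
  x$provenance <- c(x$provenance, sprintf("temperature_correct[%.1fC]", temp))
  if (temp > model$valid_max_c) x$flags <- union(x$flags, "temperature_out_of_range")
  x
}

#' Turbidity calibration
#'
#' Couples the scattered-light channel to nephelometric turbidity: the mean
#' blank-subtracted intensity in a band around 850 nm divided by
#' `counts_per_fnu` gives the turbidity in FNU, and the UV/Vis absorbance
#' contribution of turbidity is `fnu * profile(lambda)` with a default
#' `1/lambda` profile normalized at 850 nm. Compensation is valid up to
#' about 20 FNU; beyond that multiple scattering degrades it and results
#' are flagged.
#'
#' @param band_center_nm Center of the scatter integration band.
#' @param band_halfwidth_nm Half-width of the integration band, nm.
#' @param counts_per_fnu Calibration slope, band-mean counts per FNU.
#' @param absorbance_per_fnu_850 Apparent absorbance per FNU at 850 nm.
#' @param valid_max_fnu Upper validity bound of the compensation, FNU.
#' @return Object of class `turbidity_calibration`.
#' @export
turbidity_calibration <- function(band_center_nm = 850, band_halfwidth_nm = 15,
                                  counts_per_fnu = 700,
                                  absorbance_per_fnu_850 = 0.008,
                                  valid_max_fnu = 20) {
  if (counts_per_fnu <= 0) stop("counts_per_fnu must be positive")
  structure(list(band_center_nm = band_center_nm,
                 band_halfwidth_nm = band_halfwidth_nm,
                 counts_per_fnu = counts_per_fnu,
                 absorbance_per_fnu_850 = absorbance_per_fnu_850,
                 valid_max_fnu = valid_max_fnu),
            class = "turbidity_calibration")
}

#' @rdname turbidity_calibration
#' @param wavelength Wavelengths in nm.
#' @param cal A `turbidity_calibration`.
#' @return `turbidity_profile()` returns the per-FNU absorbance profile.
#' @export
turbidity_profile <- function(wavelength, cal = turbidity_calibration()) {
  cal$absorbance_per_fnu_850 * (cal$band_center_nm / wavelength)
}

scatter_band_index <- function(wavelength, cal) {
  which(abs(wavelength - cal$band_center_nm) <= cal$band_halfwidth_nm)
}

#' Estimate turbidity from the scattered-light channel
#'
#' The turbidity in FNU is the mean blank-subtracted intensity over the
#' 850 nm band divided by the calibration slope, floored at zero. A
#' saturated band makes the estimate unreliable and raises an error.
#'
#' @param sc850 Blank-subtracted `spectrum` with modality `sc850`.
#' @param cal A [turbidity_calibration()].
#' @return Turbidity in FNU (non-negative scalar).
#' @export
estimate_turbidity <- function(sc850, cal = turbidity_calibration()) {
  stopifnot(inherits(sc850, "spectrum"))
  if (sc850$modality != "sc850") stop("estimate_turbidity expects an sc850 spectrum")
  idx <- scatter_band_index(sc850$wavelength, cal)
  if (!length(idx)) stop("wavelength grid does not cover the scatter band")
  if (sc850$saturated)
    stop("scattered-light spectrum saturated: turbidity estimate unreliable")
  max(0, mean(sc850$values[idx]) / cal$counts_per_fnu)
}

#' Subtract the turbidity contribution from a UV/Vis absorbance spectrum
#'
#' `A_corr(lambda) = A(lambda) - fnu * profile(lambda)`. Above the validity
#' bound (about 20 FNU) the correction is still applied but the result is
#' flagged `turbidity_low_confidence`.
#'
#' @param absorbance An `absorbance_spectrum`.
#' @param fnu Turbidity estimate in FNU (non-negative).
#' @param cal A [turbidity_calibration()].
#' @return Compensated `absorbance_spectrum`.
#' @export
compensate_turbidity <- function(absorbance, fnu, cal = turbidity_calibration()) {
  stopifnot(inherits(absorbance, "absorbance_spectrum"))
  if (fnu < 0) stop("fnu must be non-negative")
  out <- absorbance
  out$absorbance <- absorbance$absorbance -
    fnu * turbidity_profile(absorbance$wavelength, cal)
  out$provenance <- c(out$provenance, sprintf("compensate_turbidity[%.3f FNU]", fnu))
  if (fnu > cal$valid_max_fnu)
    out$flags <- union(out$flags, "turbidity_low_confidence")
  out
}

#' Preprocess a full measurement bundle
#'
#' Runs the chain per modality: blank handling (absorbance conversion for
#' uvvis, blank subtraction plus optional baseline offset elsewhere), then
#' temperature normalization, then zero-phase low-pass filtering, then (for
#' uvvis only) turbidity compensation using the turbidity estimated from
#' the sc850 channel. Spectra lacking a temperature simply skip that step.
#'
#' @param bundle A [measurement_bundle()].
#' @param taps FIR taps from [design_lowpass()].
#' @param tmodel A [temperature_model()].
#' @param cal A [turbidity_calibration()].
#' @param baseline Logical, apply [correct_baseline()] to emission channels.
#' @return List with elements `sample_id`, `absorbance`
#'   (`absorbance_spectrum` or `NULL`), `emission` (named list of processed
#'   fl440/fl590/sc850 spectra), `fnu` (scalar or `NA`), and `warnings`
#'   (character vector of accumulated flags).
#' @export
preprocess_bundle <- function(bundle, taps = design_lowpass(),
                              tmodel = temperature_model(),
                              cal = turbidity_calibration(),
                              baseline = TRUE) {
  stopifnot(inherits(bundle, "measurement_bundle"))
  v <- validate_bundle(bundle)
  if (!v$ok)
    stop(sprintf("invalid bundle %s: %s", bundle$sample_id,
                 paste(v$issues$issue[v$issues$fatal], collapse = "; ")))
  warnings <- character()
  if (nrow(v$issues))
    warnings <- sprintf("%s: %s", v$issues$modality, v$issues$issue)

  emission <- list()
  for (m in intersect(c("fl440", "fl590", "sc850"), names(bundle$spectra))) {
    s <- subtract_blank(bundle$spectra[[m]], bundle$blanks[[m]])
    if (!is.na(s$temperature_c)) s <- temperature_correct(s, tmodel)
    if (baseline) s <- correct_baseline(s)
    s <- zero_phase_filter(s, taps)
    emission[[m]] <- s
    warnings <- c(warnings, sprintf("%s: %s", m, s$flags))
  }

  fnu <- NA_real_
  if (!is.null(emission$sc850)) fnu <- estimate_turbidity(emission$sc850, cal)

  absorbance <- NULL
  if (!is.null(bundle$spectra$uvvis)) {
    a <- compute_absorbance(bundle$spectra$uvvis, bundle$blanks$uvvis)
    if (!is.na(a$temperature_c)) a <- temperature_correct(a, tmodel)
    a <- zero_phase_filter(a, taps)
    if (!is.na(fnu)) a <- compensate_turbidity(a, fnu, cal)
    absorbance <- a
    warnings <- c(warnings, sprintf("uvvis: %s", a$flags))
  }

  list(sample_id = bundle$sample_id,
       absorbance = absorbance,
       emission = emission,
       fnu = fnu,
       warnings = unique(warnings[nzchar(warnings) &
                                  !endsWith(warnings, ": ")]))
}
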