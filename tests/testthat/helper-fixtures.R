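# Shared fixtures, all generated in code.

default_wl <- function() wavelengths(wavelength_grid())

# Single-Gaussian spectrum in counts on the default grid.
gaussian_spectrum <- function(amplitude = 1000, center = 440, width = 800,
                              modality = "fl440", baseline = 0, noise_sd = 0,
                              temperature_c = NA_real_) {
  wl <- default_wl()
  v <- baseline + amplitude * exp(-(wl - center)^2 / width)
  if (noise_sd > 0) v <- v + rnorm(length(wl), 0, noise_sd)
  new_spectrum(v, wl, modality, temperature_c = temperature_c)
}

flat_spectrum <- function(value = 100, modality = "uvvis",
                          temperature_c = NA_real_) {
  wl <- default_wl()
  new_spectrum(rep(value, length(wl)), wl, modality,
               temperature_c = temperature_c)
}

# Complete four-modality bundle with matching blanks.
complete_bundle <- function(sample_value = 500, blank_value = 100) {
  spectra <- lapply(MODALITIES, function(m) flat_spectrum(sample_value, m))
  blanks <- lapply(MODALITIES, function(m) {
    b <- flat_spectrum(blank_value, m)
    b$is_blank <- TRUE
    b
  })
  names(spectra) <- names(blanks) <- MODALITIES
  measurement_bundle("fixture", spectra, blanks)
}
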