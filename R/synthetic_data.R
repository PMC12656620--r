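#' Class labels of the assessment scheme
#'
#' Six expert classes, in report order: blue-algae presence, green-algae
#' presence, moderate turbidity, high turbidity and/or foreign substances,
#' another unknown substance, and no detectable substance.
#'
#' @format Character vector of length six.
#' @export
CLASS_LABELS <- c("blue_algae", "green_algae", "moderate_turbidity",
                  "high_turbidity_foreign", "unknown_substance",
                  "no_substance")

#' Synthetic substance band models
#'
#' Gaussian band tables (denominator-width convention, see
#' [eval_components()]) per substance and modality, with amplitudes per
#' concentration unit (percent of stock for spinach extract, mg/L for the
#' pigments). The bands encode standard pigment spectroscopy: chlorophyll
#' emission near 680/735 nm under 440 nm excitation and Soret/carotenoid/
#' red absorbance bands; C-phycocyanin emission near 650 nm under 590 nm
#' excitation, modelled as a commercial extract carrying a trace
#' chlorophyll-type impurity (weak 670 nm emission under 440 nm excitation,
#' below 10% of the 590 nm-excited response, and trace 430/675 nm
#' absorbance); uranine absorbance bands near 238, 322 and 490 nm with
#' strong 515 nm emission. Dissolved organics absorb strongly in the UV,
#' so the extract models carry broad protein/organic bands near 270-280 nm.
#' Concentrated extracts also scatter, giving each dissolved substance a
#' small 850 nm response. Pure water has no bands.
#'
#' @return Named list: per substance a list of band data frames per
#'   modality (`uvvis` amplitudes are absorbance per unit, the rest counts
#'   per unit).
#' @export
substance_models <- function() {
  band <- function(amplitude, center, width)
    data.frame(amplitude = amplitude, center = center, width = width)
  list(
    spinach = list(
      uvvis = band(c(0.030, 0.018, 0.012, 0.014),
                   c(270, 430, 470, 675), c(3000, 900, 1200, 500)),
      fl440 = band(c(500, 150), c(680, 735), c(1400, 2000)),
      fl590 = band(numeric(), numeric(), numeric()),
      sc850 = band(120, 850, 250)),
    phycocyanin = list(
      uvvis = band(c(0.0008, 0.0012, 0.0002, 0.00015),
                   c(280, 620, 430, 675), c(3000, 1000, 900, 500)),
      fl440 = band(2.5, 670, 1300),
      fl590 = band(c(30, 8), c(650, 710), c(800, 2000)),
      sc850 = band(4, 850, 250)),
    uranine = list(
      uvvis = band(c(0.010, 0.006, 0.02), c(238, 322, 490), c(1200, 1500, 700)),
      fl440 = band(400, 515, 900),
      fl590 = band(numeric(), numeric(), numeric()),
      sc850 = band(numeric(), numeric(), numeric())),
    pure_water = list(
      uvvis = band(numeric(), numeric(), numeric()),
      fl440 = band(numeric(), numeric(), numeric()),
      fl590 = band(numeric(), numeric(), numeric()),
      sc850 = band(numeric(), numeric(), numeric()))
  )
}

# Instrument blank shapes in counts (lamp envelope for uvvis, stray
# excitation light plus dark background for the emission channels).
blank_shape <- function(wavelength, modality) {
  switch(modality,
    uvvis = 2000 +
      12000 * exp(-(wavelength - 250)^2 / 3200) +
      20000 * exp(-(wavelength - 600)^2 / 125000),
    fl440 = 200 + 1500 * exp(-(wavelength - 440)^2 / 128),
    fl590 = 200 + 1500 * exp(-(wavelength - 590)^2 / 128),
    sc850 = 150 + 800 * exp(-(wavelength - 850)^2 / 200))
}

# Unit-band-mean scatter line shape at the calibration band center.
scatter_shape <- function(wavelength, cal) {
  raw <- exp(-(wavelength - cal$band_center_nm)^2 / 300)
  idx <- scatter_band_index(wavelength, cal)
  raw / mean(raw[idx])
}

#' Scenario configuration for the generator
#'
#' @param composition Named numeric vector of substance concentrations
#'   (names from [substance_models()]); all non-negative.
#' @param fnu Turbidity in FNU.
#' @param temperature_c Acquisition temperature, deg C.
#' @param noise_sd Additive Gaussian counts noise (per point).
#' @param gain_jitter_sd Relative multiplicative jitter on the substance
#'   response, emulating replicate-to-replicate variation.
#' @param seed Integer seed; fixed seed gives a bit-reproducible bundle.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(composition = c(), fnu = 0, temperature_c = 21.3,
                            noise_sd = 50, gain_jitter_sd = 0.02,
                            seed = NULL) {
  if (length(composition) && any(composition < 0))
    stop("concentrations must be non-negative")
  if (fnu < 0) stop("fnu must be non-negative")
  structure(list(composition = composition, fnu = fnu,
                 temperature_c = temperature_c, noise_sd = noise_sd,
                 gain_jitter_sd = gain_jitter_sd, seed = seed),
            class = "scenario_config")
}

#' Generate one synthetic measurement bundle
#'
#' Emulates the instrument: per modality a blank and a sample spectrum on
#' the 225-900 nm grid, where the sample adds the substance bands
#' (attenuating in UV/Vis, emitting in fluorescence/scatter), the
#' turbidity contribution (`1/lambda`-shaped apparent absorbance in UV/Vis,
#' a calibrated 850 nm scatter band, stray excitation light in the
#' fluorescence channels), the modality-specific thermal response, and
#' additive Gaussian counts noise. Counts clip at the saturation ceiling.
#' The generating class label is attached as attribute `label`.
#'
#' @param cfg A [scenario_config()].
#' @param models Substance band models, see [substance_models()].
#' @param cal A [turbidity_calibration()].
#' @param tmodel A [temperature_model()].
#' @param grid A [wavelength_grid()].
#' @param sample_id Identifier for the bundle.
#' @return A [measurement_bundle()] with attributes `label` and `config`.
#' @export
generate_bundle <- function(cfg, models = substance_models(),
                            cal = turbidity_calibration(),
                            tmodel = temperature_model(),
                            grid = wavelength_grid(),
                            sample_id = "synthetic") {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  wl <- wavelengths(grid)
  jit <- if (cfg$gain_jitter_sd > 0)
    max(0.1, 1 + stats::rnorm(1, 0, cfg$gain_jitter_sd)) else 1
  noise <- function() if (cfg$noise_sd > 0)
    stats::rnorm(length(wl), 0, cfg$noise_sd) else 0

  subst_signal <- function(modality) {
    out <- numeric(length(wl))
    for (s in names(cfg$composition)) {
      conc <- cfg$composition[[s]]
      if (conc > 0)
        out <- out + conc * eval_components(wl, models[[s]][[modality]])
    }
    out
  }
  clip <- function(v) pmin(pmax(v, 0), DEFAULT_SATURATION_COUNTS)
  mk <- function(values, modality, is_blank)
    new_spectrum(clip(values), wl, modality,
                 temperature_c = cfg$temperature_c, is_blank = is_blank)

  spectra <- list()
  blanks <- list()

  # UV/Vis: transmission attenuated by substance + turbidity absorbance,
  # the whole measured absorbance scaled by the thermal response.
  g <- temperature_response(tmodel, "uvvis", cfg$temperature_c)
  i0 <- blank_shape(wl, "uvvis")
  a_true <- jit * subst_signal("uvvis") + cfg$fnu * turbidity_profile(wl, cal)
  spectra$uvvis <- mk(i0 * 10^(-a_true * g) + noise(), "uvvis", FALSE)
  blanks$uvvis <- mk(i0 + noise(), "uvvis", TRUE)

  for (m in c("fl440", "fl590")) {
    g <- temperature_response(tmodel, m, cfg$temperature_c)
    b <- blank_shape(wl, m)
    stray_center <- if (m == "fl440") 440 else 590
    stray <- cfg$fnu * 30 * exp(-(wl - stray_center)^2 / 128)
    spectra[[m]] <- mk(b + g * (jit * subst_signal(m) + stray) + noise(), m, FALSE)
    blanks[[m]] <- mk(b + noise(), m, TRUE)
  }

  g <- temperature_response(tmodel, "sc850", cfg$temperature_c)
  b <- blank_shape(wl, "sc850")
  turb_sc <- cfg$fnu * cal$counts_per_fnu * scatter_shape(wl, cal)
  spectra$sc850 <- mk(b + g * (jit * subst_signal("sc850") + turb_sc) + noise(),
                      "sc850", FALSE)
  blanks$sc850 <- mk(b + noise(), "sc850", TRUE)

  bundle <- measurement_bundle(sample_id, spectra, blanks)
  attr(bundle, "label") <- scenario_label(cfg)
  attr(bundle, "config") <- cfg
  bundle
}

#' @rdname generate_bundle
#' @return `scenario_label()` returns the generating class label of a
#'   scenario: pigments dominate (phycocyanin marks blue algae, spinach
#'   extract green algae, uranine the unknown-substance class), otherwise
#'   turbidity decides (above 10 FNU high, from 0.5 FNU moderate), else no
#'   detectable substance.
#' @export
scenario_label <- function(cfg) {
  comp <- function(s) if (s %in% names(cfg$composition)) cfg$composition[[s]] else 0
  if (comp("phycocyanin") > 0) return("blue_algae")
  if (comp("spinach") > 0) return("green_algae")
  if (comp("uranine") > 0) return("unknown_substance")
  if (cfg$fnu > 10) return("high_turbidity_foreign")
  if (cfg$fnu >= 0.5) return("moderate_turbidity")
  "no_substance"
}

#' Generate the labeled training corpus
#'
#' Mirrors the composition of the reference-substance training campaign:
#' 40 spinach-extract spectra over a 0.25-40% dilution series, 22
#' phycocyanin solutions between 10 and 700 mg/L, 12 moderately turbid
#' samples (2-10 FNU), 12 highly turbid samples (10-20 FNU), 11 pure-water
#' samples and 22 uranine solutions (0.5-20 mg/L) - 119 bundles in six
#' classes, acquired at a nominal 22 deg C.
#'
#' @param seed Integer master seed; drives per-bundle sub-seeds so the
#'   corpus is bit-reproducible.
#' @param noise_sd,gain_jitter_sd Noise settings shared by all bundles.
#' @param temperature_c Nominal acquisition temperature.
#' @param models,cal,tmodel,grid Generator configuration, as in
#'   [generate_bundle()].
#' @return List with `bundles` (list of 119 bundles) and `labels`
#'   (character vector of generating classes).
#' @export
generate_training_corpus <- function(seed = 1, noise_sd = 50,
                                     gain_jitter_sd = 0.02,
                                     temperature_c = 22,
                                     models = substance_models(),
                                     cal = turbidity_calibration(),
                                     tmodel = temperature_model(),
                                     grid = wavelength_grid()) {
  set.seed(seed)
  scen <- list()
  add <- function(composition, fnu = 0)
    scen[[length(scen) + 1L]] <<- list(composition = composition, fnu = fnu)

  spinach_levels <- exp(seq(log(0.25), log(40), length.out = 10))
  for (lev in spinach_levels) for (r in 1:4) add(c(spinach = lev))
  phyco_levels <- exp(seq(log(10), log(700), length.out = 11))
  for (lev in phyco_levels) for (r in 1:2) add(c(phycocyanin = lev))
  for (f in stats::runif(12, 2, 10)) add(c(), fnu = f)
  for (f in stats::runif(12, 10, 20)) add(c(), fnu = f)
  for (r in 1:11) add(c())
  uranine_levels <- exp(seq(log(0.5), log(20), length.out = 11))
  for (lev in uranine_levels) for (r in 1:2) add(c(uranine = lev))

  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(scen))
  bundles <- vector("list", length(scen))
  labels <- character(length(scen))
  for (i in seq_along(scen)) {
    cfg <- scenario_config(composition = scen[[i]]$composition,
                           fnu = scen[[i]]$fnu,
                           temperature_c = temperature_c,
                           noise_sd = noise_sd,
                           gain_jitter_sd = gain_jitter_sd,
                           seed = sub_seeds[i])
    bundles[[i]] <- generate_bundle(cfg, models, cal, tmodel, grid,
                                    sample_id = sprintf("train_%03d", i))
    labels[i] <- attr(bundles[[i]], "label")
  }
  list(bundles = bundles, labels = labels)
}

#' Build the default reference library from clean synthetic standards
#'
#' Generates noiseless mid-concentration standards (25% spinach extract,
#' 85 mg/L phycocyanin, a 10 FNU turbidity standard), preprocesses them,
#' and fits Gaussian-sum references: spinach absorbance (uvvis) and
#' chlorophyll emission (fl440), phycocyanin emission (fl590), and the
#' turbidity scatter band (sc850).
#'
#' @param models,cal,tmodel,grid Generator configuration.
#' @param taps FIR taps used in preprocessing.
#' @return Named list of [reference_spectrum()] objects keyed
#'   `"substance/modality"`.
#' @export
build_reference_library <- function(models = substance_models(),
                                    cal = turbidity_calibration(),
                                    tmodel = temperature_model(),
                                    grid = wavelength_grid(),
                                    taps = design_lowpass()) {
  clean <- function(composition, fnu = 0)
    preprocess_bundle(
      generate_bundle(scenario_config(composition, fnu = fnu,
                                      noise_sd = 0, gain_jitter_sd = 0),
                      models, cal, tmodel, grid, sample_id = "reference"),
      taps = taps, tmodel = tmodel, cal = cal)

  spinach <- clean(c(spinach = 25))
  phyco <- clean(c(phycocyanin = 85))
  turb <- clean(c(), fnu = 10)

  lib <- list(
    build_reference(spinach$absorbance, substance = "spinach"),
    build_reference(spinach$emission$fl440, substance = "spinach"),
    build_reference(phyco$emission$fl590, substance = "phycocyanin"),
    build_reference(turb$emission$sc850, substance = "turbidity_standard"))
  names(lib) <- vapply(lib, function(r) library_key(r$substance, r$modality), "")
  lib
}

#' Worked-example feature vectors from the field campaigns
#'
#' The R^2 feature vectors of the published field measurements (three
#' August objects; three September objects each for the laboratory setup
#' and the submersible probe), as printed. These are fixed inputs for the
#' classifier worked examples; the September R^2 at 590 nm is zero by the
#' poor-fit convention.
#'
#' @return Data frame with columns `campaign`, `object`, `r2_440`,
#'   `r2_590`, `r2_850`, `r2_uvvis`.
#' @export
generate_worked_example_features <- function() {
  data.frame(
    campaign = rep(c("august", "september_lab", "september_probe"), each = 3),
    object = rep(1:3, 3),
    r2_440 = c(0.7679, 0.7202, 0.7206,
               0.8365, 0.8291, 0.8654,
               0.8894, 0.8765, 0.8840),
    r2_590 = c(0.9627, 0.9605, 0.9571, rep(0, 6)),
    r2_850 = c(0.9287, 0.9512, 0.9490,
               0.9553, 0.9667, 0.9632,
               0.6294, 0.5236, 0.4003),
    r2_uvvis = c(0.4017, 0.3394, 0.3605,
                 0.6750, 0.6646, 0.6534,
                 0.4553, 0.5337, 0.5861),
    stringsAsFactors = FALSE)
}
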