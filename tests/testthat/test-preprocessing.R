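test_that("absorbance conversion follows the Beer-Lambert log ratio", {
  blank <- flat_spectrum(100); blank$is_blank <- TRUE
  a <- compute_absorbance(flat_spectrum(10), blank)
  expect_equal(a$absorbance, rep(1, length(a$absorbance)), tolerance = 1e-12)
  self <- compute_absorbance(flat_spectrum(100), blank)
  expect_equal(self$absorbance, rep(0, length(self$absorbance)), tolerance = 1e-12)
})

test_that("absorbance is additive along chained media and antisymmetric", {
  s1000 <- flat_spectrum(1000); s100 <- flat_spectrum(100); s10 <- flat_spectrum(10)
  a12 <- compute_absorbance(s100, s1000)$absorbance
  a23 <- compute_absorbance(s10, s100)$absorbance
  a13 <- compute_absorbance(s10, s1000)$absorbance
  expect_equal(a12 + a23, a13, tolerance = 1e-12)
  expect_equal(a13[1], 2, tolerance = 1e-12)
  expect_equal(compute_absorbance(s1000, s100)$absorbance,
               -compute_absorbance(s100, s1000)$absorbance, tolerance = 1e-12)
})

test_that("absorbance rejects bad blanks and flags clipped samples", {
  wl <- default_wl()
  bad_blank <- new_spectrum(c(0, rep(100, length(wl) - 1)), wl, "uvvis")
  expect_error(compute_absorbance(flat_spectrum(10), bad_blank), "calibration")
  v <- rep(50, length(wl)); v[5] <- 0
  a <- compute_absorbance(new_spectrum(v, wl, "uvvis"), flat_spectrum(100))
  expect_true("clipped_nonpositive_sample" %in% a$flags)
  expect_true(all(is.finite(a$absorbance)))
  expect_error(compute_absorbance(flat_spectrum(10, "fl440"),
                                  flat_spectrum(100, "fl440")), "uvvis")
})

test_that("blank subtraction preserves sign information", {
  f <- subtract_blank(flat_spectrum(500, "fl440"), flat_spectrum(100, "fl440"))
  expect_equal(f$values, rep(400, length(f$values)))
  z <- subtract_blank(flat_spectrum(100, "fl590"), flat_spectrum(100, "fl590"))
  expect_equal(z$values, rep(0, length(z$values)))
  neg <- subtract_blank(flat_spectrum(80, "sc850"), flat_spectrum(100, "sc850"))
  expect_true(all(neg$values < 0))
  expect_true("negative_values" %in% neg$flags)
  expect_error(subtract_blank(flat_spectrum(1, "fl440"), flat_spectrum(1, "fl590")),
               "modality mismatch")
})

test_that("baseline correction fixes systematic shifts but not noise quantiles", {
  set.seed(5)
  shifted <- gaussian_spectrum(baseline = -500, noise_sd = 20)
  fixed <- correct_baseline(shifted)
  expect_lt(abs(stats::quantile(fixed$values, 0.05)), 100)
  noisy <- gaussian_spectrum(noise_sd = 20)
  expect_equal(correct_baseline(noisy)$values, noisy$values)
})

test_that("the low-pass design has unit DC gain, symmetry and a falling response", {
  taps <- design_lowpass()
  expect_length(taps, 31L)
  expect_equal(sum(taps), 1, tolerance = 1e-9)
  expect_equal(taps, rev(taps), tolerance = 1e-12)
  mag <- function(f) Mod(sum(taps * exp(-2i * pi * f * seq_along(taps))))
  expect_lt(mag(0.4), mag(0.05))
  expect_gt(mag(0.05), 0.98)          # passband essentially flat
  expect_lt(mag(0.4), 0.01)           # deep in the stopband
  expect_error(filter_spec(passband_frac = 0.3, stopband_frac = 0.2),
               "passband_frac < stopband_frac")
})

test_that("zero-phase filtering preserves DC, peak position, and linearity", {
  taps <- design_lowpass()
  const <- rep(7, 451)
  expect_equal(zero_phase_filter(const, taps), const, tolerance = 1e-9)

  peak <- gaussian_spectrum(center = 500, width = 800)
  filt <- zero_phase_filter(peak, taps)
  expect_identical(which.max(filt$values), which.max(peak$values))

  set.seed(11)
  x <- rnorm(451); y <- rnorm(451)
  lhs <- zero_phase_filter(2.5 * x - 1.25 * y, taps)
  rhs <- 2.5 * zero_phase_filter(x, taps) - 1.25 * zero_phase_filter(y, taps)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  expect_error(zero_phase_filter(rnorm(50), taps), "too short")
})

test_that("high-frequency oscillations are crushed by the bidirectional filter", {
  osc <- sin(2 * pi * 0.45 * seq_len(451))
  taps <- design_lowpass()
  out <- zero_phase_filter(osc, taps)
  # the odd-symmetric extension anchors the first/last samples to the data,
  # so attenuation is judged away from one filter length at each edge
  interior <- seq(length(taps) + 1L, length(osc) - length(taps))
  expect_lt(sqrt(mean(out[interior]^2)), 0.01 * sqrt(mean(osc^2)))
})

test_that("temperature normalization recovers the reference-temperature spectrum", {
  tm <- temperature_model()
  ref <- gaussian_spectrum(temperature_c = 21.3)
  expect_equal(temperature_correct(ref, tm)$values, ref$values, tolerance = 1e-12)

  # generate at 25 C with the model's own linear drift, then correct
  drift <- 1 + tm$slopes[["fl440"]] * (25 - 21.3)
  warm <- gaussian_spectrum(temperature_c = 25)
  warm$values <- warm$values * drift
  rec <- temperature_correct(warm, tm)
  expect_equal(rec$values, gaussian_spectrum()$values, tolerance = 1e-3)

  hot <- gaussian_spectrum(temperature_c = 32)
  out <- temperature_correct(hot, tm)
  expect_true("temperature_out_of_range" %in% out$flags)
  expect_true(all(is.finite(out$values)))
  expect_error(temperature_correct(gaussian_spectrum(), tm), "temperature")
})

test_that("turbidity estimation inverts the calibration slope", {
  cal <- turbidity_calibration()
  wl <- default_wl()
  expect_equal(estimate_turbidity(new_spectrum(rep(0, length(wl)), wl, "sc850"), cal), 0)
  idx <- abs(wl - 850) <= cal$band_halfwidth_nm
  flat_band <- new_spectrum(ifelse(idx, cal$counts_per_fnu, 0), wl, "sc850")
  expect_equal(estimate_turbidity(flat_band, cal), 1, tolerance = 1e-12)

  b <- generate_bundle(scenario_config(c(), fnu = 12, noise_sd = 50,
                                       gain_jitter_sd = 0, seed = 3))
  p <- preprocess_bundle(b)
  expect_equal(p$fnu, 12, tolerance = 0.1)
  sat <- new_spectrum(rep(40000, length(wl)), wl, "sc850")
  expect_error(estimate_turbidity(sat, cal), "saturated")
})

test_that("turbidity compensation removes an additively constructed contribution", {
  cal <- turbidity_calibration()
  wl <- default_wl()
  pure <- 0.3 * exp(-(wl - 430)^2 / 900)
  mixed <- structure(list(wavelength = wl,
                          absorbance = pure + 8 * turbidity_profile(wl, cal),
                          flags = character(), temperature_c = NA_real_,
                          provenance = character()),
                     class = "absorbance_spectrum")
  rec <- compensate_turbidity(mixed, 8, cal)
  expect_equal(rec$absorbance, pure, tolerance = 1e-6)
  expect_false("turbidity_low_confidence" %in% rec$flags)

  same <- compensate_turbidity(mixed, 0, cal)
  expect_equal(same$absorbance, mixed$absorbance)

  flagged <- compensate_turbidity(mixed, 25, cal)
  expect_true("turbidity_low_confidence" %in% flagged$flags)
})

test_that("the preprocessing chain is deterministic and recovers pure absorbance", {
  # uranine does not scatter at 850 nm, so the turbidity estimate is clean
  # and the compensated absorbance can be compared to the pure truth
  cfg <- scenario_config(c(uranine = 10), fnu = 8, temperature_c = 25,
                         noise_sd = 50, gain_jitter_sd = 0, seed = 77)
  p1 <- preprocess_bundle(generate_bundle(cfg))
  p2 <- preprocess_bundle(generate_bundle(cfg))
  expect_identical(p1$absorbance$absorbance, p2$absorbance$absorbance)
  expect_identical(p1$emission$fl440$values, p2$emission$fl440$values)

  truth <- eval_components(default_wl(), substance_models()$uranine$uvvis) * 10
  err <- p1$absorbance$absorbance - truth
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(truth^2)), 0.05)
})
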