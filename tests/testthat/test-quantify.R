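test_that("default windows reproduce the assay's integration ranges", {
  hf <- default_windows("high_field")
  bt <- default_windows("benchtop")
  expect_equal(hf$sucrose, c(5.54, 5.32))
  expect_equal(bt$sucrose, c(5.54, 5.32))
  expect_equal(hf$alpha_glucose, c(5.29, 5.16))
  expect_equal(hf$beta_glucose, c(4.63, 4.53))
  expect_equal(hf$fructose, c(4.10, 4.07))
  expect_equal(hf$citrate, c(3.02, 2.73))
  expect_equal(bt$citrate, c(2.81, 2.54))
  expect_error(default_windows("bench"), "unknown")
})

test_that("custom windows must not overlap among sugars", {
  expect_error(integration_windows(c(5.54, 5.32), c(5.40, 5.16),
                                   c(4.63, 4.53), c(4.10, 4.07),
                                   c(3.02, 2.73)), "overlap")
})

# simple spectrum on a uniform descending grid for integration geometry tests
flat_spectrum <- function(y, from = 6, to = 2) {
  n <- length(y)
  nmr_spectrum(seq(from, to, length.out = n), y, sample_id = "synthetic")
}

test_that("window integration has the expected geometry", {
  n <- 4001L
  ppm <- seq(6, 2, length.out = n)
  expect_equal(integrate_window(flat_spectrum(numeric(n)), c(5.5, 5.0)), 0)
  # unit-height rectangle of width 0.1 ppm fully inside the window
  y <- as.numeric(ppm <= 4.55 & ppm >= 4.45)
  expect_equal(integrate_window(flat_spectrum(y), c(4.8, 4.2)), 0.1,
               tolerance = abs(diff(ppm[1:2])) / 0.1)
  # window bounds are order-invariant
  spec <- flat_spectrum(y)
  expect_identical(integrate_window(spec, c(4.2, 4.8)),
                   integrate_window(spec, c(4.8, 4.2)))
  expect_error(integrate_window(spec, c(9, 8)), "outside")
  expect_error(integrate_window(spec, c(4.5001, 4.5)), "fewer than 3")
})

test_that("a synthetic Lorentzian integrates to its analytic area", {
  n <- 20001L
  ppm <- seq(6, 2, length.out = n)
  w <- 0.01  # FWHM in ppm
  y <- (1 / pi) * (w / 2) / ((ppm - 4.5)^2 + (w / 2)^2)  # unit-area Lorentzian
  spec <- flat_spectrum(y)
  got <- integrate_window(spec, c(5.0, 4.0))
  expected <- lorentz_window_integral(4.5, w, 4.0, 5.0)
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("relative areas anchor sucrose to exactly 1", {
  # rectangles of known area in each marker window: raw areas
  # (2.0, 0.8, 1.4, 3.0, 0.5) -> relatives (1.00, 0.40, 0.70, 1.50, 0.25)
  n <- 64001L
  ppm <- seq(6, 2, length.out = n)
  rect <- function(c0, hw, h) h * as.numeric(abs(ppm - c0) <= hw)
  y <- rect(5.43, 0.05, 20) + rect(5.22, 0.04, 10) + rect(4.58, 0.035, 20) +
    rect(4.085, 0.0125, 120) + rect(2.875, 0.025, 10)
  spec <- flat_spectrum(y)
  ra <- relative_areas(spec, default_windows("high_field"))
  expect_identical(ra$sucrose, 1.00)
  expect_equal(ra$alpha_glucose, 0.40, tolerance = 0.01)
  expect_equal(ra$beta_glucose, 0.70, tolerance = 0.01)
  expect_equal(ra$fructose, 1.50, tolerance = 0.01)
  expect_equal(ra$citrate, 0.25, tolerance = 0.01)
})

test_that("quantification guards on unusable integrals", {
  n <- 8001L
  ppm <- seq(6, 2, length.out = n)
  zero <- nmr_spectrum(ppm, numeric(n), sample_id = "s")
  expect_error(relative_areas(zero, default_windows("high_field")), "sucrose")
  y <- as.numeric(abs(ppm - 5.43) <= 0.05) -
    0.5 * as.numeric(abs(ppm - 2.875) <= 0.05)
  neg <- nmr_spectrum(ppm, y, sample_id = "s")
  expect_error(relative_areas(neg, default_windows("high_field")), "citrate")
})

test_that("relative areas are invariant to overall intensity scaling", {
  comp <- composition_from_ratio(8, shift_jitter_scale = 0)
  fid <- synthesize_fid(comp, scheme_high_field(), noise_sd = 0, seed = 1)
  spec <- process_fid(fid, processing_params(phase_mode = list(ph0 = 0, ph1 = 0)))
  ra1 <- relative_areas(spec, default_windows("high_field"))
  spec$real <- spec$real * 37.5
  ra2 <- relative_areas(spec, default_windows("high_field"))
  for (nm in c("alpha_glucose", "beta_glucose", "fructose", "citrate"))
    expect_equal(ra2[[nm]], ra1[[nm]], tolerance = 1e-12)
})

test_that("measured relative areas match the capture-fraction oracle", {
  # oracle: closed-form Lorentzian window integrals over every transition,
  # including off-window leakage — independent of the FFT/trapezoid path.
  # Compared on a finely zero-filled grid with the exact (jitter-free) axis,
  # so that trapezoid discretisation of the 1.9 Hz benchtop fructose window
  # does not enter (that protocol-grid effect is covered by the
  # field-equivalence tests).
  for (sch in list(scheme_high_field(), scheme_benchtop())) {
    comp <- composition_from_ratio(8, shift_jitter_scale = 0,
                                   citrate_center_offset =
                                     default_citrate_offset(sch))
    fid <- synthesize_fid(comp, sch, noise_sd = 0, seed = 1)
    spec <- phase_correct(
      apodize_zerofill_transform(fid, processing_params(zero_fill_to = 2L^20)),
      list(ph0 = 0, ph1 = 0))
    win <- default_windows(sch$field_tag)
    got <- relative_areas(spec, win)
    want <- expected_relative_areas(comp, sch, win)
    for (nm in c("alpha_glucose", "beta_glucose", "fructose", "citrate"))
      expect_equal(got[[nm]], want[[nm]], tolerance = 0.03,
                   label = sprintf("%s (%s)", nm, sch$field_tag))
  }
})

test_that("the optional proton-normalised mode divides by multiplicities", {
  comp <- composition_from_ratio(8, shift_jitter_scale = 0)
  fid <- synthesize_fid(comp, scheme_high_field(), noise_sd = 0, seed = 1)
  spec <- process_fid(fid, processing_params(phase_mode = list(ph0 = 0, ph1 = 0)))
  raw <- relative_areas(spec, default_windows("high_field"))
  nrm <- relative_areas(spec, default_windows("high_field"), normalized = TRUE)
  expect_equal(nrm$fructose, raw$fructose / 2, tolerance = 1e-12)
  expect_equal(nrm$citrate, raw$citrate / 4, tolerance = 1e-12)
  expect_identical(nrm$sucrose, 1.00)
})
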