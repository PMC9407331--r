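test_that("lb = 0 reproduces a plain zero-filled transform", {
  fid <- singlet_fixture(n_points = 4096L, noise_sd = 0.01)
  spec <- apodize_zerofill_transform(fid, processing_params(
    zero_fill_to = 8192L, exponential_lb = 0))
  # independent transform: halve first point, zero-fill, FFT, shift, flip
  y <- fid$complex_signal
  y[1] <- y[1] / 2
  y <- c(y, rep(0 + 0i, 8192 - 4096))
  ref <- stats::fft(y)[c(4097:8192, 1:4096)]
  expect_equal(spec$real, rev(Re(ref)), tolerance = 1e-12)
  expect_equal(spec$imag, rev(Im(ref)), tolerance = 1e-12)
})

test_that("a 32 K acquisition zero-fills to 64 K output points", {
  fid <- singlet_fixture(n_points = 32768L)
  spec <- apodize_zerofill_transform(fid, processing_params(zero_fill_to = 65536L))
  expect_length(spec$ppm, 65536L)
  expect_length(spec$real, 65536L)
  expect_error(apodize_zerofill_transform(
    fid, processing_params(zero_fill_to = 16384L)), "smaller")
})

test_that("0.3 Hz apodization adds 0.3 Hz to the Lorentzian linewidth", {
  fid <- singlet_fixture(shift = 5.40, lw = 1.0, n_points = 32768L)
  spec <- apodize_zerofill_transform(fid, processing_params(
    zero_fill_to = 65536L, exponential_lb = 0.3))
  sf <- fid$scheme$spectrometer_frequency
  # interpolated half-height crossings
  y <- spec$real; x <- spec$ppm * sf
  i0 <- which.max(y); hm <- y[i0] / 2
  li <- max(which(y[1:(i0 - 1)] <= hm))
  ri <- i0 + min(which(y[(i0 + 1):length(y)] <= hm))
  xl <- stats::approx(y[c(li, li + 1)], x[c(li, li + 1)], hm)$y
  xr <- stats::approx(y[c(ri - 1, ri)], x[c(ri - 1, ri)], hm)$y
  fwhm <- abs(xl - xr)
  expect_equal(fwhm, 1.3, tolerance = 0.05)
})

test_that("zero filling preserves total spectral energy", {
  fid <- singlet_fixture(n_points = 4096L, noise_sd = 0.005)
  energy <- function(nz) {
    sp <- apodize_zerofill_transform(fid, processing_params(
      zero_fill_to = nz, exponential_lb = 0))
    sum(sp$real^2 + sp$imag^2) * (fid$scheme$spectral_width / nz)
  }
  expect_equal(energy(4096L), energy(16384L), tolerance = 1e-10)
})

test_that("fixed zero phases leave the spectrum unchanged", {
  fid <- singlet_fixture(n_points = 4096L, noise_sd = 0.01)
  spec <- apodize_zerofill_transform(fid, processing_params(zero_fill_to = 8192L))
  out <- phase_correct(spec, list(ph0 = 0, ph1 = 0))
  expect_equal(out$real, spec$real, tolerance = 1e-12)
})

test_that("auto phasing is a fixed point on an absorption-mode spectrum", {
  comp <- extract_composition(1, 0, 0, 0, hdo = 0)
  fid <- synthesize_fid(comp, fast_scheme(n_points = 8192L),
                        line_list = spread_line_list(),
                        noise_sd = 0.001, seed = 3)
  spec <- apodize_zerofill_transform(fid, processing_params(zero_fill_to = 16384L))
  out <- phase_correct(spec, "auto")
  h <- out$history[[length(out$history)]]
  expect_lt(abs(h$ph0), 1)
})

test_that("auto phasing recovers known dephasing angles", {
  comp <- extract_composition(1, 0, 0, 0, hdo = 0)
  fid <- synthesize_fid(comp, fast_scheme(n_points = 8192L),
                        line_list = spread_line_list(),
                        noise_sd = 0.001, seed = 3)
  spec <- apodize_zerofill_transform(fid, processing_params(zero_fill_to = 16384L))
  for (tp in list(c(-35, -60), c(80, 40))) {
    deph <- phase_correct(spec, list(ph0 = tp[1], ph1 = tp[2]))
    rec <- phase_correct(deph, "auto")
    h <- rec$history[[length(rec$history)]]
    err0 <- abs(((h$ph0 + tp[1] + 180) %% 360) - 180)
    err1 <- abs(h$ph1 + tp[2])
    expect_lt(err0, 2)
    expect_lt(err1, 10)
  }
})

test_that("baseline correction is near-identity on a flat baseline", {
  fid <- singlet_fixture(n_points = 8192L, noise_sd = 0.002, seed = 5)
  spec <- phase_correct(apodize_zerofill_transform(
    fid, processing_params(zero_fill_to = 16384L)), list(ph0 = 0, ph1 = 0))
  out <- baseline_correct(spec, "iterative")
  expect_lt(max(abs(out$real - spec$real)), 0.01 * max(spec$real))
})

test_that("an injected linear ramp is removed", {
  fid <- singlet_fixture(n_points = 8192L, noise_sd = 0.002, seed = 5)
  spec <- phase_correct(apodize_zerofill_transform(
    fid, processing_params(zero_fill_to = 16384L)), list(ph0 = 0, ph1 = 0))
  peak <- max(spec$real)
  ramp <- seq(-0.2, 0.3, length.out = length(spec$real)) * peak
  spec$real <- spec$real + ramp
  out <- baseline_correct(spec, list(mode = "polynomial", order = 3L))
  # signal-free window far from the 5.40 ppm singlet
  sel <- out$ppm < 0 & out$ppm > -2
  expect_lt(mean(abs(out$real[sel])), 0.01 * peak)
})

test_that("baseline mode 'none' only records a no-op", {
  fid <- singlet_fixture(n_points = 4096L)
  spec <- apodize_zerofill_transform(fid, processing_params(zero_fill_to = 8192L))
  out <- baseline_correct(spec, "none")
  expect_identical(out$real, spec$real)
  expect_equal(out$history[[length(out$history)]]$step, "baseline")
})

test_that("referencing shifts the axis by the expected amount", {
  fid <- singlet_fixture(shift = 5.30, n_points = 8192L, noise_sd = 0.001)
  spec <- phase_correct(apodize_zerofill_transform(
    fid, processing_params(zero_fill_to = 16384L)), list(ph0 = 0, ph1 = 0))
  out <- reference_spectrum(spec, target = 5.22, search_window = c(5.40, 5.20))
  h <- out$history[[length(out$history)]]
  dppm <- abs(diff(spec$ppm[1:2]))
  expect_lt(abs(h$shift_ppm + 0.08), 2 * dppm)
  # referenced peak now sits at the target within a digital-resolution step
  expect_lt(abs(out$ppm[which.max(out$real)] - 5.22), dppm)
  # re-referencing an already-referenced spectrum is a no-op
  again <- reference_spectrum(out, target = 5.22, search_window = c(5.30, 5.14))
  expect_lt(abs(again$history[[length(again$history)]]$shift_ppm), dppm)
})

test_that("referencing fails loudly when no peak is present", {
  fid <- synthesize_fid(extract_composition(0, 0, 0, 0, hdo = 0),
                        fast_scheme(n_points = 4096L), noise_sd = 0.01,
                        seed = 2)
  spec <- apodize_zerofill_transform(fid, processing_params(zero_fill_to = 8192L))
  expect_error(reference_spectrum(spec, 5.22, c(5.32, 5.10)), "no peak")
})

test_that("alignment leaves identical spectra untouched", {
  fid <- singlet_fixture(n_points = 4096L, noise_sd = 0.001, seed = 9)
  spec <- phase_correct(apodize_zerofill_transform(
    fid, processing_params(zero_fill_to = 8192L)), list(ph0 = 0, ph1 = 0))
  out <- align_spectra(list(spec, spec, spec))
  for (s in out) {
    h <- s$history[[length(s$history)]]
    expect_equal(h$lag_ppm, 0)
  }
})

test_that("alignment recovers a known injected displacement", {
  comp <- composition_from_ratio(8, shift_jitter_scale = 0)
  fid <- synthesize_fid(comp, scheme_high_field(), seed = 21)
  spec <- phase_correct(apodize_zerofill_transform(
    fid, processing_params()), list(ph0 = 0, ph1 = 0))
  dppm <- abs(diff(spec$ppm[1:2]))
  k <- round(0.02 / dppm)  # +0.02 ppm displacement in grid steps
  disp <- spec
  disp$real <- c(spec$real[-seq_len(k)], numeric(k))
  disp$imag <- c(spec$imag[-seq_len(k)], numeric(k))
  specs <- align_spectra(list(spec, spec, spec, spec, disp),
                         region = c(6, 2))
  h <- specs[[5]]$history[[length(specs[[5]]$history)]]
  expect_lt(abs(h$lag_ppm + 0.02), 1.5 * dppm)
  # round trip: marker integrals agree with the undisplaced truth within 1%
  w <- default_windows("high_field")
  for (nm in names(w)) {
    a0 <- integrate_window(spec, w[[nm]])
    a1 <- integrate_window(specs[[5]], w[[nm]])
    expect_equal(a1, a0, tolerance = 0.01)
  }
  # total intensity conserved by the rigid shift
  expect_equal(sum(specs[[5]]$real), sum(disp$real),
               tolerance = 1e-3)
})

test_that("processing is purely functional", {
  comp <- composition_from_ratio(7)
  fid <- synthesize_fid(comp, fast_scheme(n_points = 8192L), seed = 13)
  p <- processing_params(zero_fill_to = 16384L,
                         phase_mode = list(ph0 = 0, ph1 = 0))
  s1 <- process_fid(fid, p)
  s2 <- process_fid(fid, p)
  expect_identical(s1$real, s2$real)
  expect_identical(s1$ppm, s2$ppm)
})

test_that("end-to-end integrals are proportional to amount x proton count", {
  mk <- function(amount) {
    ll <- list(spin_signal("sucrose", 5.40, list(type = "singlet"), 1L))
    comp <- extract_composition(amount, 0, 0, 0, hdo = 0)
    fid <- synthesize_fid(comp, scheme_high_field(), line_list = ll,
                          noise_sd = 0, seed = 1)
    spec <- process_fid(fid, processing_params(
      phase_mode = list(ph0 = 0, ph1 = 0)))
    integrate_window(spec, c(5.54, 5.32))
  }
  expect_equal(mk(2) / mk(1), 2, tolerance = 0.005)
})
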