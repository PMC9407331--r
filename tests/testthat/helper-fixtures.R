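# Shared fixtures and independent oracles for the test suite.

# A short high-field-like scheme for fast unit tests (full 32 K acquisitions
# are exercised where the protocol sizes matter).
fast_scheme <- function(n_points = 4096L, sf = 400.13, sw = 8000,
                        lw = 1.0, tag = "high_field") {
  acquisition_scheme(sf, sw, n_points, n_scans = 1L, flip_angle = 90,
                     natural_linewidth_hz = lw, field_tag = tag)
}

# Composition with a single analyte carrying one singlet, for lineshape tests
singlet_fixture <- function(shift = 5.40, lw = 1.0, n_points = 32768L,
                            noise_sd = 0, seed = 1L, scheme = NULL) {
  ll <- list(spin_signal("sucrose", shift, list(type = "singlet"), 1L))
  comp <- extract_composition(1, 0, 0, 0, hdo = 0)
  scheme <- scheme %||% fast_scheme(n_points = n_points, lw = lw)
  synthesize_fid(comp, scheme, line_list = ll, noise_sd = noise_sd,
                 seed = seed)
}

# Line list with peaks spread over most of the spectral width: an
# identifiable design for zero/first-order phase recovery
spread_line_list <- function() {
  list(spin_signal("sucrose", 12.0, list(type = "singlet"), 1L),
       spin_signal("sucrose", 8.0, list(type = "singlet"), 1L),
       spin_signal("sucrose", 1.5, list(type = "singlet"), 1L),
       spin_signal("sucrose", -2.0, list(type = "singlet"), 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles ----------------------------------------------------

# Closed-form integral of a unit-area Lorentzian (FWHM w, centre p, all in the
# same frequency units) over [a, b]
lorentz_window_integral <- function(p, w, a, b) {
  (atan(2 * (b - p) / w) - atan(2 * (a - p) / w)) / pi
}

# Expected marker-window integrals for a composition, from the closed-form
# Lorentzian window integrals of every line-list transition (including
# off-window leakage), independent of the FFT/trapezoid pipeline. Returns
# sucrose-anchored relative areas.
expected_relative_areas <- function(comp, scheme, windows,
                                    line_list = default_line_list(),
                                    lb = 0.3) {
  sf <- scheme$spectrometer_frequency
  w_hz <- scheme$natural_linewidth_hz + lb
  amounts <- c(sucrose = comp$sucrose, glucose = comp$glucose_total,
               fructose = comp$fructose_total, citrate = comp$citric_acid,
               hdo = comp$hdo)
  frac_of <- function(sig) {
    a <- comp$alpha_glucose_fraction
    bf <- comp$beta_furanose_fructose_fraction
    switch(sig$species, alpha = a, beta = 1 - a, beta_furanose = bf,
           beta_pyranose = max(0, 1 - bf - 0.06),
           alpha_furanose = sig$species_fraction, sig$species_fraction)
  }
  out <- vapply(names(windows), function(nm) {
    win <- windows[[nm]]
    a_hz_lo <- min(win) * sf
    a_hz_hi <- max(win) * sf
    total <- 0
    for (sig in line_list) {
      amt <- amounts[[sig$metabolite]]
      if (amt == 0) next
      center <- sig$center_shift +
        if (sig$metabolite == "citrate") comp$citrate_center_offset else 0
      tr <- signal_transitions(sig, sf)
      for (k in seq_len(nrow(tr))) {
        p_hz <- center * sf + tr$offset_hz[k]
        total <- total + amt * sig$proton_count * frac_of(sig) *
          tr$weight[k] *
          lorentz_window_integral(p_hz, w_hz, a_hz_lo, a_hz_hi)
      }
    }
    total
  }, numeric(1))
  out / out[["sucrose"]]
}

# Two-spin AB oracle: diagonalise the spin Hamiltonian (Hz units) and return
# single-quantum transition magnitudes and intensities, independently of the
# closed form in ab_transitions()
ab_oracle <- function(J, delta_nu) {
  nuA <- delta_nu / 2
  nuB <- -delta_nu / 2
  # basis aa, ab, ba, bb; Iz eigenvalues +/- 1/2
  H <- diag(c((nuA + nuB) / 2 + J / 4,
              (nuA - nuB) / 2 - J / 4,
              (-nuA + nuB) / 2 - J / 4,
              (-nuA - nuB) / 2 + J / 4))
  H[2, 3] <- H[3, 2] <- J / 2
  e <- eigen(H, symmetric = TRUE)
  # total I- (lowering) operator in the product basis
  Im_op <- matrix(0, 4, 4)
  Im_op[2, 1] <- Im_op[3, 1] <- 1  # aa -> ab, ba
  Im_op[4, 2] <- Im_op[4, 3] <- 1  # ab, ba -> bb
  V <- e$vectors
  T_op <- t(V) %*% Im_op %*% V
  freq <- numeric(0); int <- numeric(0)
  for (i in 1:4) for (j in 1:4) {
    if (abs(T_op[i, j]) > 1e-12) {
      freq <- c(freq, abs(e$values[j] - e$values[i]))
      int <- c(int, T_op[i, j]^2)
    }
  }
  o <- order(freq)
  data.frame(freq = freq[o], weight = int[o] / sum(int))
}

# Independent OLS via nested grid search on the sum of squared errors
grid_search_ols <- function(x, y, slope_range = c(-5, 5),
                            intercept_range = c(-20, 20), rounds = 8L,
                            n_grid = 41L) {
  sr <- slope_range; ir <- intercept_range
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    ss <- seq(sr[1], sr[2], length.out = n_grid)
    is <- seq(ir[1], ir[2], length.out = n_grid)
    sse <- outer(ss, is, Vectorize(function(b, a) sum((y - a - b * x)^2)))
    k <- arrayInd(which.min(sse), dim(sse))
    best <- c(ss[k[1]], is[k[2]])
    ds <- diff(sr) / (n_grid - 1); di <- diff(ir) / (n_grid - 1)
    sr <- best[1] + c(-2, 2) * ds
    ir <- best[2] + c(-2, 2) * di
  }
  c(slope = best[1], intercept = best[2])
}
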