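#' Describe one resonance (or spin pattern) of an analyte
#'
#' A spin signal is the generator's unit of spectral content: a chemical-shift
#' centre, a multiplet pattern, a proton count and the fraction of the analyte
#' present as the species carrying the signal (for example the alpha anomer of
#' glucose). Marker signals are the five resonances used for quantification;
#' non-marker ("crowd") signals reproduce the congested 3.0-4.3 ppm sugar
#' region that makes low-field spectra hard to read.
#'
#' @param metabolite Analyte the signal belongs to: one of `"sucrose"`,
#'   `"glucose"`, `"fructose"`, `"citrate"` or `"hdo"`.
#' @param center_shift Chemical shift of the pattern centre, in ppm.
#' @param pattern A list describing the multiplet: `list(type = "singlet")`,
#'   `list(type = "doublet", J = <Hz>)`,
#'   `list(type = "first_order_multiplet", J = c(<Hz>, ...))` or
#'   `list(type = "ab_system", J = <Hz>, delta_shift = <ppm>)`.
#' @param proton_count Number of protons giving rise to the signal (>= 1).
#' @param species_fraction Fraction of the analyte present as this species,
#'   in (0, 1]. For glucose anomers and fructose tautomers this default is
#'   overridden at synthesis time by the corresponding
#'   [extract_composition()] fractions.
#' @param species Species label used for that override: `""` (none),
#'   `"alpha"`/`"beta"` (glucose anomers), `"beta_furanose"`,
#'   `"beta_pyranose"` or `"alpha_furanose"` (fructose tautomers).
#' @param marker Marker-window name this signal is quantified in
#'   (`"sucrose"`, `"alpha_glucose"`, `"beta_glucose"`, `"fructose"`,
#'   `"citrate"`) or `NA` for crowd signals.
#'
#' @return An object of class `spin_signal`.
#' @export
spin_signal <- function(metabolite, center_shift, pattern, proton_count,
                        species_fraction = 1, species = "",
                        marker = NA_character_) {
  metabolite <- match.arg(metabolite,
                          c("sucrose", "glucose", "fructose", "citrate", "hdo"))
  if (!is_scalar_num(center_shift)) stopf("'center_shift' must be a ppm value")
  if (!is.list(pattern) || is.null(pattern$type))
    stopf("'pattern' must be a list with a 'type' element")
  pattern$type <- match.arg(pattern$type,
                            c("singlet", "doublet", "first_order_multiplet",
                              "ab_system"))
  if (pattern$type %in% c("doublet", "first_order_multiplet", "ab_system")) {
    if (is.null(pattern$J) || any(!is.finite(pattern$J)) || any(pattern$J < 0))
      stopf("pattern '%s' needs finite J >= 0 (Hz)", pattern$type)
  }
  if (pattern$type == "ab_system" &&
      (!is_scalar_num(pattern$delta_shift) || pattern$delta_shift < 0))
    stopf("an AB system needs 'delta_shift' >= 0 (ppm)")
  if (!is_count(proton_count)) stopf("'proton_count' must be a positive integer")
  if (!is_scalar_num(species_fraction) ||
      species_fraction <= 0 || species_fraction > 1)
    stopf("'species_fraction' must be in (0, 1]")
  structure(
    list(metabolite = metabolite, center_shift = center_shift,
         pattern = pattern, proton_count = as.integer(proton_count),
         species_fraction = species_fraction, species = species,
         marker = marker),
    class = "spin_signal"
  )
}

#' Exact transition list of a two-spin AB system
#'
#' Solves the coupled two-spin problem in closed form. With chemical-shift
#' separation `delta_nu` (Hz), coupling `J` (Hz) and
#' `C = sqrt(delta_nu^2 + J^2)`, the four lines sit at `+/-(C +/- J)/2` around
#' the pattern centre, as two doublets with splitting `J` whose centres are
#' separated by `C`. The inner lines carry relative intensity `1 + J/C`, the
#' outer lines `1 - J/C` (the familiar "roofing" that collapses the pattern
#' towards a singlet as `delta_nu -> 0`).
#'
#' @param J Scalar coupling in Hz (>= 0).
#' @param delta_nu Chemical-shift difference between the two nuclei, in Hz.
#' @return A data frame with columns `offset_hz` (position relative to the
#'   pattern centre) and `weight` (intensities, normalised to sum to 1).
#' @export
ab_transitions <- function(J, delta_nu) {
  if (!is_scalar_num(J) || J < 0) stopf("'J' must be >= 0 Hz")
  if (!is_scalar_num(delta_nu) || delta_nu < 0) stopf("'delta_nu' must be >= 0 Hz")
  C <- sqrt(delta_nu^2 + J^2)
  if (C == 0) return(data.frame(offset_hz = 0, weight = 1))
  off <- c(-(C + J) / 2, -(C - J) / 2, (C - J) / 2, (C + J) / 2)
  wt <- c(1 - J / C, 1 + J / C, 1 + J / C, 1 - J / C)
  data.frame(offset_hz = off, weight = wt / sum(wt))
}

#' Stick transitions of a spin signal at a given spectrometer frequency
#'
#' Expands a [spin_signal()] pattern into individual transitions. First-order
#' splittings are field-invariant in Hz (so field-dependent in ppm); the AB
#' pattern uses the exact two-spin solution of [ab_transitions()], whose shape
#' depends strongly on the field because `delta_nu` scales with it.
#'
#' @param signal A [spin_signal()].
#' @param spectrometer_frequency 1H frequency in MHz.
#' @return Data frame with `offset_hz` (relative to the pattern centre) and
#'   `weight` (summing to 1).
#' @export
signal_transitions <- function(signal, spectrometer_frequency) {
  stopifnot(inherits(signal, "spin_signal"))
  p <- signal$pattern
  switch(p$type,
    singlet = data.frame(offset_hz = 0, weight = 1),
    doublet = data.frame(offset_hz = c(-p$J / 2, p$J / 2), weight = c(0.5, 0.5)),
    first_order_multiplet = {
      tr <- data.frame(offset_hz = 0, weight = 1)
      for (J in p$J) {
        tr <- data.frame(
          offset_hz = c(tr$offset_hz - J / 2, tr$offset_hz + J / 2),
          weight = c(tr$weight, tr$weight) / 2
        )
      }
      aggregate(weight ~ offset_hz, tr, sum)[, c("offset_hz", "weight")]
    },
    ab_system = ab_transitions(p$J, p$delta_shift * spectrometer_frequency)
  )
}

#' Default line list for aqueous mandarin-extract spectra
#'
#' The five marker resonances used for quantification, plus (optionally) the
#' crowded non-marker sugar ring protons and the residual HDO line. Marker
#' centres follow the standard assignments for sugars and citrate in D2O:
#' sucrose glucosyl anomeric proton at 5.40 ppm (d, J = 3.8 Hz), alpha-glucose
#' anomeric at 5.22 ppm (d, 3.7 Hz), beta-glucose anomeric at 4.63 ppm
#' (d, 7.9 Hz), the unresolved H-3/H-4 cluster of the beta-furanose form of
#' fructose at 4.09 ppm (2H) and the four citrate methylene protons as an AB
#' system (J = 15.7 Hz, delta-delta 0.13 ppm) centred at 2.875 ppm at 298 K
#' (the centre moves with temperature and pH; see
#' [extract_composition()]'s `citrate_center_offset`).
#'
#' Crowd signals use literature shifts for the non-anomeric ring protons of
#' sucrose, both glucose anomers and the fructose tautomers; they are what
#' merges into the 3.0-4.3 ppm hump at 60 MHz while leaving the marker
#' windows usable.
#'
#' @param include_crowd Include the non-marker ring-proton signals (default
#'   `TRUE`; they are required for realistic low-field overlap).
#' @param include_hdo Include the residual HDO singlet at 4.70 ppm, which is
#'   excluded from every integration window.
#' @param alpha_furanose_fraction Fraction of total fructose present as the
#'   alpha-furanose tautomer (literature equilibrium value).
#' @return A list of [spin_signal()] objects.
#' @export
default_line_list <- function(include_crowd = TRUE, include_hdo = TRUE,
                              alpha_furanose_fraction = 0.06) {
  s <- function(...) spin_signal(...)
  d <- function(J) list(type = "doublet", J = J)
  sg <- function() list(type = "singlet")
  ll <- list(
    s("sucrose", 5.40, d(3.8), 1L, marker = "sucrose"),
    s("glucose", 5.22, d(3.7), 1L, species_fraction = 0.36, species = "alpha",
      marker = "alpha_glucose"),
    s("glucose", 4.63, d(7.9), 1L, species_fraction = 0.64, species = "beta",
      marker = "beta_glucose"),
    s("fructose", 4.09, list(type = "first_order_multiplet", J = 1.0), 2L,
      species_fraction = 0.25, species = "beta_furanose", marker = "fructose"),
    s("citrate", 2.875, list(type = "ab_system", J = 15.7, delta_shift = 0.13),
      4L, marker = "citrate")
  )
  if (include_crowd) {
    crowd <- list(
      # sucrose glucosyl + fructosyl ring protons
      s("sucrose", 3.56, sg(), 1L), s("sucrose", 3.76, sg(), 1L),
      s("sucrose", 3.47, sg(), 1L), s("sucrose", 3.84, sg(), 1L),
      s("sucrose", 3.82, sg(), 2L), s("sucrose", 3.67, sg(), 2L),
      s("sucrose", 4.21, sg(), 1L), s("sucrose", 4.05, sg(), 1L),
      s("sucrose", 3.88, sg(), 1L), s("sucrose", 3.81, sg(), 2L),
      # alpha-glucose ring
      s("glucose", 3.53, sg(), 1L, 0.36, "alpha"),
      s("glucose", 3.70, sg(), 1L, 0.36, "alpha"),
      s("glucose", 3.40, sg(), 1L, 0.36, "alpha"),
      s("glucose", 3.82, sg(), 1L, 0.36, "alpha"),
      s("glucose", 3.77, sg(), 2L, 0.36, "alpha"),
      # beta-glucose ring
      s("glucose", 3.24, sg(), 1L, 0.64, "beta"),
      s("glucose", 3.48, sg(), 1L, 0.64, "beta"),
      s("glucose", 3.40, sg(), 1L, 0.64, "beta"),
      s("glucose", 3.46, sg(), 1L, 0.64, "beta"),
      s("glucose", 3.72, sg(), 2L, 0.64, "beta"),
      # beta-furanose fructose, non-marker protons
      s("fructose", 3.59, sg(), 2L, 0.25, "beta_furanose"),
      s("fructose", 3.82, sg(), 1L, 0.25, "beta_furanose"),
      s("fructose", 3.67, sg(), 2L, 0.25, "beta_furanose"),
      # beta-pyranose fructose (dominant tautomer)
      s("fructose", 3.70, sg(), 2L, 0.69, "beta_pyranose"),
      s("fructose", 3.79, sg(), 1L, 0.69, "beta_pyranose"),
      s("fructose", 3.89, sg(), 1L, 0.69, "beta_pyranose"),
      s("fructose", 3.99, sg(), 1L, 0.69, "beta_pyranose"),
      s("fructose", 4.02, sg(), 1L, 0.69, "beta_pyranose"),
      s("fructose", 3.71, sg(), 1L, 0.69, "beta_pyranose"),
      # alpha-furanose fructose (minor tautomer; H-3/H-4 fall near the
      # fructose marker window, as in real extracts)
      s("fructose", 4.11, sg(), 1L, alpha_furanose_fraction, "alpha_furanose"),
      s("fructose", 4.00, sg(), 1L, alpha_furanose_fraction, "alpha_furanose"),
      s("fructose", 3.72, sg(), 3L, alpha_furanose_fraction, "alpha_furanose")
    )
    ll <- c(ll, crowd)
  }
  if (include_hdo) ll <- c(ll, list(s("hdo", 4.70, sg(), 1L)))
  ll
}
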