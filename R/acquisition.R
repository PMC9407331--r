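#' Describe an NMR acquisition scheme
#'
#' An acquisition scheme bundles the instrument settings that determine how a
#' free-induction decay (FID) is recorded: the 1H spectrometer frequency, the
#' spectral width, the number of complex time-domain points, the number of
#' co-added scans, the excitation flip angle and the inter-scan relaxation
#' delay. Two ready-made schemes mirror a typical high-field acquisition
#' ([scheme_high_field()]) and a benchtop acquisition ([scheme_benchtop()]).
#'
#' @param spectrometer_frequency 1H frequency in MHz (> 0).
#' @param spectral_width Sweep width in Hz (> 0).
#' @param n_points Number of complex time-domain points (>= 1024).
#' @param n_scans Number of co-added scans (>= 1).
#' @param flip_angle Excitation pulse angle in degrees, in (0, 90].
#' @param relaxation_delay Inter-scan delay in seconds (>= 0).
#' @param temperature_label Free-text description of the sample temperature.
#' @param natural_linewidth_hz Default full width at half maximum (Hz) of the
#'   simulated resonances before apodization. Benchtop magnets are typically
#'   less homogeneous, hence the larger default in [scheme_benchtop()].
#' @param field_tag One of `"high_field"`, `"benchtop"` or `"custom"`; selects
#'   the matching citrate integration window in [default_windows()].
#'
#' @return An object of class `acquisition_scheme`.
#' @seealso [synthesize_fid()], [default_windows()]
#' @export
acquisition_scheme <- function(spectrometer_frequency,
                               spectral_width,
                               n_points,
                               n_scans = 1L,
                               flip_angle = 90,
                               relaxation_delay = 1,
                               temperature_label = "unspecified",
                               natural_linewidth_hz = 1.0,
                               field_tag = "custom") {
  if (!is_scalar_num(spectrometer_frequency) || spectrometer_frequency <= 0)
    stopf("'spectrometer_frequency' must be a positive number (MHz)")
  if (!is_scalar_num(spectral_width) || spectral_width <= 0)
    stopf("'spectral_width' must be a positive number (Hz)")
  if (!is_count(n_points, min = 1024L))
    stopf("'n_points' must be an integer >= 1024")
  if (!is_count(n_scans))
    stopf("'n_scans' must be a positive integer")
  if (!is_scalar_num(flip_angle) || flip_angle <= 0 || flip_angle > 90)
    stopf("'flip_angle' must be in (0, 90] degrees")
  if (!is_scalar_num(relaxation_delay) || relaxation_delay < 0)
    stopf("'relaxation_delay' must be >= 0 seconds")
  if (!is_scalar_num(natural_linewidth_hz) || natural_linewidth_hz <= 0)
    stopf("'natural_linewidth_hz' must be > 0 Hz")
  field_tag <- match.arg(field_tag, c("high_field", "benchtop", "custom"))
  structure(
    list(
      spectrometer_frequency = spectrometer_frequency,
      spectral_width = spectral_width,
      n_points = as.integer(n_points),
      n_scans = as.integer(n_scans),
      flip_angle = flip_angle,
      relaxation_delay = relaxation_delay,
      temperature_label = temperature_label,
      natural_linewidth_hz = natural_linewidth_hz,
      field_tag = field_tag
    ),
    class = "acquisition_scheme"
  )
}

#' @rdname acquisition_scheme
#' @export
scheme_high_field <- function() {
  acquisition_scheme(
    spectrometer_frequency = 400.13,
    spectral_width = 8000,
    n_points = 32768L,
    n_scans = 64L,
    flip_angle = 30,
    relaxation_delay = 1,
    temperature_label = "298 K",
    natural_linewidth_hz = 1.0,
    field_tag = "high_field"
  )
}

#' @rdname acquisition_scheme
#' @export
scheme_benchtop <- function() {
  acquisition_scheme(
    spectrometer_frequency = 62.32,
    spectral_width = 5000,
    n_points = 32768L,
    n_scans = 256L,
    flip_angle = 90,
    relaxation_delay = 1,
    temperature_label = "room temperature",
    natural_linewidth_hz = 1.5,
    field_tag = "benchtop"
  )
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf(
    "<acquisition_scheme [%s]> %.2f MHz, sw %.0f Hz, %d pts, %d scans, %g deg pulse, d1 %gs (%s)\n",
    x$field_tag, x$spectrometer_frequency, x$spectral_width, x$n_points,
    x$n_scans, x$flip_angle, x$relaxation_delay, x$temperature_label
  ))
  invisible(x)
}
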