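#' Construct a frequency-domain spectrum object
#'
#' A spectrum is a ppm axis (strictly descending, the usual left-to-right NMR
#' convention), the real (absorption) intensities, optionally the imaginary
#' part, the acquisition scheme, and an append-only processing history.
#'
#' @param ppm Numeric ppm axis, strictly descending.
#' @param real Real-part intensities, same length as `ppm`.
#' @param imag Imaginary part (or `NULL` once discarded after phasing).
#' @param scheme The [acquisition_scheme()] the data were recorded under.
#' @param sample_id Sample identifier.
#' @param carrier_ppm Carrier position used to anchor the axis.
#' @param history List of processing-step descriptors.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, real, imag = NULL, scheme = NULL,
                         sample_id = "sample", carrier_ppm = NA_real_,
                         history = list()) {
  if (length(ppm) != length(real))
    stopf("'ppm' and 'real' must have equal length")
  if (!is.null(imag) && length(imag) != length(real))
    stopf("'imag' must match 'real' in length")
  if (any(diff(ppm) >= 0)) stopf("'ppm' axis must be strictly descending")
  structure(
    list(ppm = as.numeric(ppm), real = as.numeric(real),
         imag = if (is.null(imag)) NULL else as.numeric(imag),
         scheme = scheme, sample_id = sample_id, carrier_ppm = carrier_ppm,
         history = history),
    class = "nmr_spectrum"
  )
}

#' @noRd
add_history <- function(spec, step, ...) {
  spec$history <- c(spec$history, list(c(list(step = step), list(...))))
  spec
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum '%s'> %d points, %.2f to %.2f ppm, %d processing steps\n",
              x$sample_id, length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              length(x$history)))
  for (h in x$history) cat("  -", h$step, "\n")
  invisible(x)
}

#' @export
as.data.frame.nmr_spectrum <- function(x, ...) {
  d <- data.frame(ppm = x$ppm, real = x$real)
  if (!is.null(x$imag)) d$imag <- x$imag
  d
}

#' Plot a spectrum with the conventional reversed ppm axis
#'
#' @param x An `nmr_spectrum`.
#' @param xlim Optional ppm range (plotted high to low).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nmr_spectrum <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) xlim <- range(x$ppm)
  graphics::plot(x$ppm, x$real, type = "l", xlim = rev(sort(xlim)),
                 xlab = "chemical shift (ppm)", ylab = "intensity",
                 main = x$sample_id, ...)
  invisible(x)
}
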