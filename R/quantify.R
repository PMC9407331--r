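#' Marker integration windows
#'
#' The five fixed integration ranges used for quantification. The four sugar
#' windows are identical at both fields — sucrose glucosyl anomeric
#' 5.54-5.32 ppm, alpha-glucose anomeric 5.29-5.16 ppm, beta-glucose anomeric
#' 4.63-4.53 ppm and the fructose beta-furanose H-3/H-4 cluster
#' 4.10-4.07 ppm — while the citrate methylene window is field-specific
#' (3.02-2.73 ppm at high field, 2.81-2.54 ppm on the benchtop instrument,
#' reflecting the temperature-dependent citrate position).
#'
#' @param field_tag `"high_field"` or `"benchtop"`.
#' @return An object of class `integration_windows`: a named list of
#'   `(ppm_high, ppm_low)` pairs with a `field_tag` attribute.
#' @export
default_windows <- function(field_tag = c("high_field", "benchtop")) {
  if (length(field_tag) == 1L &&
      !field_tag %in% c("high_field", "benchtop"))
    stopf("unknown field tag '%s'", field_tag)
  field_tag <- match.arg(field_tag)
  citrate <- if (field_tag == "high_field") c(3.02, 2.73) else c(2.81, 2.54)
  integration_windows(
    sucrose = c(5.54, 5.32),
    alpha_glucose = c(5.29, 5.16),
    beta_glucose = c(4.63, 4.53),
    fructose = c(4.10, 4.07),
    citrate = citrate,
    field_tag = field_tag
  )
}

#' @rdname default_windows
#' @param sucrose,alpha_glucose,beta_glucose,fructose,citrate ppm pairs
#'   (either order) for custom window sets.
#' @export
integration_windows <- function(sucrose, alpha_glucose, beta_glucose,
                                fructose, citrate, field_tag = "custom") {
  w <- list(sucrose = normalize_window(sucrose),
            alpha_glucose = normalize_window(alpha_glucose),
            beta_glucose = normalize_window(beta_glucose),
            fructose = normalize_window(fructose),
            citrate = normalize_window(citrate))
  sugars <- w[c("sucrose", "alpha_glucose", "beta_glucose", "fructose")]
  for (i in 1:3) for (j in (i + 1):4) {
    a <- sugars[[i]]; b <- sugars[[j]]
    if (a[2] < b[1] && b[2] < a[1])
      stopf("sugar windows '%s' and '%s' overlap",
            names(sugars)[i], names(sugars)[j])
  }
  structure(w, field_tag = field_tag, class = "integration_windows")
}

#' @export
print.integration_windows <- function(x, ...) {
  cat(sprintf("<integration_windows [%s]>\n", attr(x, "field_tag")))
  for (nm in names(x))
    cat(sprintf("  %-14s %5.2f to %5.2f ppm\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Trapezoidal integral of the real part over a ppm window
#'
#' @param spec An [nmr_spectrum()].
#' @param window ppm pair (either order).
#' @return Raw area in intensity x ppm units.
#' @export
integrate_window <- function(spec, window) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  w <- normalize_window(window)
  rng <- range(spec$ppm)
  if (w[1] > rng[2] || w[2] < rng[1])
    stopf("window [%g, %g] lies outside the spectral range [%g, %g]",
          w[2], w[1], rng[1], rng[2])
  sel <- which(spec$ppm <= w[1] & spec$ppm >= w[2])
  if (length(sel) < 3L)
    stopf("fewer than 3 grid points inside window [%g, %g]", w[2], w[1])
  trapezoid(spec$ppm[sel], spec$real[sel])
}

#' Sucrose-anchored relative areas of the five marker windows
#'
#' Integrates each marker window and scales all raw areas so the sucrose
#' glucosyl anomeric signal takes the arbitrary value 1.00 exactly. No
#' proton-count or tautomer-fraction normalisation is applied: the assay
#' scales raw areas only (an optional `normalized` mode divides each area by
#' its marker proton count for diagnostics, but is off by default and not
#' used by the scoring model).
#'
#' @param spec An [nmr_spectrum()], processed and referenced.
#' @param windows An [integration_windows()] set matching the instrument.
#' @param normalized If `TRUE`, additionally divide each area by the marker's
#'   proton count (1, 1, 1, 2, 4). Off by default.
#' @return An object of class `relative_areas`: named list with `sucrose`
#'   (exactly 1), `alpha_glucose`, `beta_glucose`, `fructose`, `citrate` and
#'   the `sample_id`.
#' @export
relative_areas <- function(spec, windows, normalized = FALSE) {
  stopifnot(inherits(spec, "nmr_spectrum"),
            inherits(windows, "integration_windows"))
  raw <- vapply(names(windows), function(nm) integrate_window(spec, windows[[nm]]),
                numeric(1))
  if (raw[["sucrose"]] <= 0)
    stopf("sucrose integral <= 0: sample '%s' unusable", spec$sample_id)
  neg <- names(raw)[raw < 0]
  if (length(neg))
    stopf("negative integral in window(s) %s for sample '%s'",
          paste(neg, collapse = ", "), spec$sample_id)
  rel <- raw / raw[["sucrose"]]
  if (normalized) {
    protons <- c(sucrose = 1, alpha_glucose = 1, beta_glucose = 1,
                 fructose = 2, citrate = 4)
    rel <- rel / protons[names(rel)]
    rel <- rel / rel[["sucrose"]]
  }
  rel[["sucrose"]] <- 1.00
  structure(as.list(rel), sample_id = spec$sample_id,
            field_tag = attr(windows, "field_tag"), class = "relative_areas")
}

#' @export
print.relative_areas <- function(x, ...) {
  cat(sprintf("<relative_areas '%s'> suc 1.00 | aGlc %.3f | bGlc %.3f | Fru %.3f | Cit %.3f\n",
              attr(x, "sample_id"), x$alpha_glucose, x$beta_glucose,
              x$fructose, x$citrate))
  invisible(x)
}
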