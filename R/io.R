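#' Write a spectrum to disk
#'
#' Two plain-text formats are supported. `"columnar"` is a commented
#' tab-separated table (`ppm`, `real`, and `imag` when present) with the
#' acquisition metadata in `# key: value` header lines — lossless for this
#' package's purposes. `"jcamp"` writes the real part as a minimal JCAMP-DX
#' 5.01 NMR-spectrum record (AFFN `(X++(Y..Y))` XYDATA on a uniform ppm
#' grid); the imaginary part is not representable there and is dropped.
#'
#' @param spec An [nmr_spectrum()].
#' @param path Output path.
#' @param format `"columnar"` or `"jcamp"`; default guessed from the file
#'   extension (`.jdx`/`.dx` give JCAMP).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = NULL) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  format <- format %||% guess_format(path)
  switch(match.arg(format, c("columnar", "jcamp")),
         columnar = write_spectrum_columnar(spec, path),
         jcamp = write_spectrum_jcamp(spec, path))
  invisible(path)
}

#' Read a spectrum from disk
#'
#' Counterpart of [write_spectrum()]. ppm axes stored in ascending order are
#' normalised to the package's descending convention on read.
#'
#' @param path Input path.
#' @param format `"columnar"`, `"jcamp"`, or `NULL` to guess from the
#'   extension.
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  format <- format %||% guess_format(path)
  switch(match.arg(format, c("columnar", "jcamp")),
         columnar = read_spectrum_columnar(path),
         jcamp = read_spectrum_jcamp(path))
}

#' @noRd
guess_format <- function(path) {
  if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "columnar"
}

#' @noRd
scheme_header_lines <- function(scheme, carrier_ppm, sample_id) {
  c(sprintf("# sample_id: %s", sample_id),
    sprintf("# carrier_ppm: %.6g", carrier_ppm),
    if (!is.null(scheme)) c(
      sprintf("# spectrometer_frequency_mhz: %.6g", scheme$spectrometer_frequency),
      sprintf("# spectral_width_hz: %.6g", scheme$spectral_width),
      sprintf("# n_points: %d", scheme$n_points),
      sprintf("# n_scans: %d", scheme$n_scans),
      sprintf("# flip_angle_deg: %.6g", scheme$flip_angle),
      sprintf("# field_tag: %s", scheme$field_tag)))
}

#' @noRd
parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[m[2]]] <- m[3]
  out
}

#' @noRd
write_spectrum_columnar <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(scheme_header_lines(spec$scheme, spec$carrier_ppm, spec$sample_id), con)
  has_imag <- !is.null(spec$imag)
  writeLines(paste(c("ppm", "real", if (has_imag) "imag"), collapse = "\t"), con)
  d <- cbind(spec$ppm, spec$real, if (has_imag) spec$imag)
  utils::write.table(format(d, digits = 10, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @noRd
read_spectrum_columnar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("empty spectrum file: %s", path)
  h <- parse_header(lines)
  body <- grep("^[^#]", lines, value = TRUE)
  if (length(body) < 2L) stopf("no data rows in %s", path)
  cols <- strsplit(body[1], "\t")[[1]]
  if (!identical(cols[1:2], c("ppm", "real")))
    stopf("malformed columnar spectrum (header row '%s') in %s", body[1], path)
  d <- utils::read.table(text = body[-1], sep = "\t", col.names = cols)
  if (any(!is.finite(d$ppm)) || any(!is.finite(d$real)))
    stopf("non-numeric data in %s", path)
  o <- order(d$ppm, decreasing = TRUE)
  scheme <- header_scheme(h)
  nmr_spectrum(d$ppm[o], d$real[o],
               imag = if ("imag" %in% cols) d$imag[o] else NULL,
               scheme = scheme,
               sample_id = h$sample_id %||% basename(path),
               carrier_ppm = as.numeric(h$carrier_ppm %||% NA),
               history = list(list(step = "read", path = path)))
}

#' @noRd
header_scheme <- function(h) {
  if (is.null(h$spectrometer_frequency_mhz)) return(NULL)
  acquisition_scheme(
    spectrometer_frequency = as.numeric(h$spectrometer_frequency_mhz),
    spectral_width = as.numeric(h$spectral_width_hz),
    n_points = as.integer(h$n_points),
    n_scans = as.integer(h$n_scans %||% 1),
    flip_angle = as.numeric(h$flip_angle_deg %||% 90),
    field_tag = h$field_tag %||% "custom")
}

#' @noRd
write_spectrum_jcamp <- function(spec, path) {
  n <- length(spec$ppm)
  # JCAMP stores ascending X; our axis is descending ppm
  x <- rev(spec$ppm)
  y <- rev(spec$real)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("##TITLE= %s", spec$sample_id)
  w("##JCAMP-DX= 5.01")
  w("##DATA TYPE= NMR SPECTRUM")
  w("##DATA CLASS= XYDATA")
  w("##ORIGIN= citrusnmr")
  w("##OWNER= citrusnmr")
  if (!is.null(spec$scheme)) {
    w("##.OBSERVE FREQUENCY= %.6f", spec$scheme$spectrometer_frequency)
    w("##.OBSERVE NUCLEUS= ^1H")
  }
  w("##XUNITS= PPM")
  w("##YUNITS= ARBITRARY UNITS")
  w("##XFACTOR= 1.0")
  w("##YFACTOR= 1.0")
  w("##FIRSTX= %.10g", x[1])
  w("##LASTX= %.10g", x[n])
  w("##NPOINTS= %d", n)
  w("##FIRSTY= %.10g", y[1])
  w("##XYDATA= (X++(Y..Y))")
  per <- 6L
  for (i in seq(1L, n, by = per)) {
    j <- min(i + per - 1L, n)
    w("%s", paste(c(sprintf("%.10g", x[i]), sprintf("%.9g", y[i:j])),
                  collapse = " "))
  }
  w("##END=")
}

#' @noRd
read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("empty JCAMP file: %s", path)
  if (!any(grepl("^##JCAMP-DX", lines))) stopf("not a JCAMP-DX file: %s", path)
  ldr <- function(name) {
    m <- grep(paste0("^##", name, "= *"), lines, value = TRUE)
    if (length(m) == 0L) return(NULL)
    sub(paste0("^##", name, "= *"), "", m[1])
  }
  i0 <- grep("^##XYDATA=", lines)
  if (length(i0) != 1L) stopf("missing XYDATA block in %s", path)
  i1 <- grep("^##END", lines)
  i1 <- i1[i1 > i0][1]
  if (is.na(i1)) stopf("missing ##END in %s", path)
  body <- lines[(i0 + 1L):(i1 - 1L)]
  if (length(body) == 0L) stopf("empty XYDATA block in %s", path)
  xf <- as.numeric(ldr("XFACTOR") %||% "1")
  yf <- as.numeric(ldr("YFACTOR") %||% "1")
  npts <- as.integer(ldr("NPOINTS") %||% NA)
  firstx <- as.numeric(ldr("FIRSTX"))
  lastx <- as.numeric(ldr("LASTX"))
  ys <- numeric(0)
  for (ln in body) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(tok) < 2L) stopf("malformed XYDATA line '%s' in %s", ln, path)
    vals <- suppressWarnings(as.numeric(tok))
    if (any(is.na(vals))) stopf("non-numeric token in XYDATA line '%s'", ln)
    ys <- c(ys, vals[-1])
  }
  if (!is.na(npts) && length(ys) != npts)
    stopf("NPOINTS (%d) does not match data (%d) in %s", npts, length(ys), path)
  n <- length(ys)
  x <- seq(firstx, lastx, length.out = n) * xf
  y <- ys * yf
  o <- order(x, decreasing = TRUE)
  sf <- as.numeric(ldr("\\.OBSERVE FREQUENCY") %||% NA)
  nmr_spectrum(x[o], y[o], imag = NULL, scheme = NULL,
               sample_id = ldr("TITLE") %||% basename(path),
               carrier_ppm = NA_real_,
               history = list(list(step = "read", path = path,
                                   observe_frequency = sf)))
}

#' Write / read an FID as columnar text
#'
#' Tab-separated `index`, `real`, `imag` with the acquisition scheme in
#' commented header lines, so a written FID can be fully reconstructed.
#'
#' @param fid A `fid_record`.
#' @param path File path.
#' @return `path` (write) or a `fid_record` (read).
#' @export
write_fid <- function(fid, path) {
  stopifnot(inherits(fid, "fid_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(scheme_header_lines(fid$scheme, fid$carrier_ppm, fid$sample_id), con)
  writeLines(sprintf("# seed: %d", fid$seed), con)
  writeLines("index\treal\timag", con)
  d <- cbind(seq_along(fid$complex_signal),
             Re(fid$complex_signal), Im(fid$complex_signal))
  utils::write.table(format(d, digits = 10, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fid
#' @export
read_fid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("empty FID file: %s", path)
  h <- parse_header(lines)
  scheme <- header_scheme(h)
  if (is.null(scheme)) stopf("FID file %s lacks acquisition metadata", path)
  body <- grep("^[^#]", lines, value = TRUE)
  d <- utils::read.table(text = body[-1], sep = "\t",
                         col.names = strsplit(body[1], "\t")[[1]])
  structure(
    list(complex_signal = complex(real = d$real, imaginary = d$imag),
         scheme = scheme, ground_truth = NULL,
         sample_id = h$sample_id %||% basename(path),
         seed = as.integer(h$seed %||% NA),
         carrier_ppm = as.numeric(h$carrier_ppm %||% 4.7)),
    class = "fid_record")
}
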