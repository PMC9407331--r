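# Internal helpers shared across modules.

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Trapezoidal integral of y over x (x need not be sorted; sign-normalised)
#' @noRd
trapezoid <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' Normalise a (high, low) or (low, high) ppm pair to c(high, low)
#' @noRd
normalize_window <- function(w) {
  if (length(w) != 2L || !all(is.finite(w))) stopf("window must be two finite ppm values")
  c(max(w), min(w))
}

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' @noRd
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
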