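#' Relative sweetness weights
#'
#' The Schiffman-type relative sweetness factors used to convert sugar
#' contents into a sweetening power: 1.0 for sucrose, 1.3 for fructose and
#' 0.6 for glucose (applied to both anomers).
#'
#' @param sucrose,fructose,glucose Positive weights.
#' @return An object of class `sweetness_weights`.
#' @export
sweetness_weights <- function(sucrose = 1.0, fructose = 1.3, glucose = 0.6) {
  w <- c(sucrose = sucrose, fructose = fructose, glucose = glucose)
  if (any(!vapply(w, is_scalar_num, logical(1))) || any(w <= 0))
    stopf("all sweetness weights must be > 0")
  structure(as.list(w), class = "sweetness_weights")
}

#' Sweetening power of a sample
#'
#' The sweetness-weighted sum of the sugar contents:
#' `w_suc * sucrose + w_glc * (alpha_glucose + beta_glucose) +
#'  w_fru * fructose`, on the sucrose-anchored relative-area scale.
#'
#' @param areas A [relative_areas()] object (or named list with the five
#'   marker areas).
#' @param weights A [sweetness_weights()].
#' @return A single unitless number.
#' @export
sweetening_power <- function(areas, weights = sweetness_weights()) {
  stopifnot(inherits(weights, "sweetness_weights"))
  weights$sucrose * areas$sucrose +
    weights$glucose * (areas$alpha_glucose + areas$beta_glucose) +
    weights$fructose * areas$fructose
}

#' Sweetening-power/citric-acid ratio
#'
#' The scalar that predicts acceptability: [sweetening_power()] divided by
#' the citrate relative area. Because every term is anchored to sucrose, the
#' ratio is invariant to any overall rescaling of the five areas.
#'
#' @inheritParams sweetening_power
#' @return A single unitless number.
#' @export
sweetness_acid_ratio <- function(areas, weights = sweetness_weights()) {
  if (!is_scalar_num(areas$citrate) || areas$citrate <= 0)
    stopf("citrate relative area must be > 0")
  sweetening_power(areas, weights) / areas$citrate
}

#' Score a processed cohort into per-replicate ratios
#'
#' @param specs List of processed spectra (with `variety_id`/`replicate`
#'   fields, as returned by [process_cohort()]).
#' @param windows An [integration_windows()] set.
#' @param weights A [sweetness_weights()].
#' @return Data frame with columns `sample_id`, `variety_id`, `replicate`,
#'   the five relative areas and `ratio`.
#' @export
score_cohort <- function(specs, windows, weights = sweetness_weights()) {
  rows <- lapply(specs, function(s) {
    ra <- relative_areas(s, windows)
    data.frame(sample_id = attr(ra, "sample_id"),
               variety_id = if (is.null(s$variety_id)) NA_character_ else s$variety_id,
               replicate = if (is.null(s$replicate)) NA_integer_ else s$replicate,
               sucrose = ra$sucrose, alpha_glucose = ra$alpha_glucose,
               beta_glucose = ra$beta_glucose, fructose = ra$fructose,
               citrate = ra$citrate,
               ratio = sweetness_acid_ratio(ra, weights))
  })
  do.call(rbind, rows)
}

#' Aggregate per-replicate ratios to variety level
#'
#' Mirrors the assay's replicate handling: the per-variety ratio entering the
#' regression is the arithmetic mean over replicates; the per-variety
#' relative standard deviation (RSD, %) is reported alongside.
#'
#' @param scored Data frame from [score_cohort()].
#' @return Data frame with `variety_id`, `mean_ratio`, `rsd_percent`, `n_rep`.
#' @export
aggregate_varieties <- function(scored) {
  stopifnot(is.data.frame(scored), all(c("variety_id", "ratio") %in% names(scored)))
  sp <- split(scored$ratio, scored$variety_id)
  out <- data.frame(
    variety_id = names(sp),
    mean_ratio = vapply(sp, mean, numeric(1)),
    rsd_percent = vapply(sp, function(r)
      if (length(r) > 1L) 100 * stats::sd(r) / mean(r) else NA_real_, numeric(1)),
    n_rep = vapply(sp, length, integer(1))
  )
  rownames(out) <- NULL
  out
}

#' Fit the linear acceptability model
#'
#' Ordinary least squares of the consumer acceptability score on the
#' per-variety mean sweetening-power/citric-acid ratio. The reported
#' R-squared is the coefficient of determination; the RMSE uses divisor `n`
#' (not `n - 2`), i.e. the root mean square of the in-sample residuals, which
#' is the convention the printed assay figures follow.
#'
#' @param varieties A data frame with columns `acceptability` and
#'   `mean_ratio` (plus optionally `variety_id`), e.g. from
#'   [aggregate_varieties()] joined with panel scores — or a numeric vector
#'   of ratios if `acceptability` is given separately.
#' @param acceptability Optional numeric vector of panel scores when
#'   `varieties` is a ratio vector.
#' @return An object of class `acceptability_model` with components `slope`,
#'   `intercept`, `r_squared`, `rmse`, `n`, `fitted_values`, `residuals`,
#'   `data` and the underlying `lm` fit.
#' @examples
#' t1 <- mandarin_table1()
#' fit <- fit_acceptability_model(t1$ratio_400, t1$acceptability)
#' fit
#' predict(fit, ratio = 8.0)
#' @export
fit_acceptability_model <- function(varieties, acceptability = NULL) {
  if (is.numeric(varieties)) {
    stopifnot(is.numeric(acceptability))
    varieties <- data.frame(mean_ratio = varieties,
                            acceptability = acceptability)
  }
  stopifnot(is.data.frame(varieties),
            all(c("mean_ratio", "acceptability") %in% names(varieties)))
  d <- varieties
  if (nrow(d) < 3L) stopf("at least 3 varieties are required")
  if (any(!is.finite(d$mean_ratio)) || any(!is.finite(d$acceptability)))
    stopf("non-finite ratio or acceptability")
  if (stats::var(d$mean_ratio) == 0)
    stopf("degenerate design: all ratios equal")
  fit <- stats::lm(acceptability ~ mean_ratio, data = d)
  res <- stats::residuals(fit)
  sst <- sum((d$acceptability - mean(d$acceptability))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = 1 - sum(res^2) / sst,
         rmse = sqrt(mean(res^2)),
         n = nrow(d),
         fitted_values = unname(stats::fitted(fit)),
         residuals = unname(res),
         data = d,
         lm = fit),
    class = "acceptability_model"
  )
}

#' @export
print.acceptability_model <- function(x, digits = 3, ...) {
  cat("Linear acceptability model (OLS on variety mean ratios)\n")
  cat(sprintf("  acceptability = %.*f + %.*f * ratio   (n = %d)\n",
              digits, x$intercept, digits, x$slope, x$n))
  cat(sprintf("  R-squared = %.*f, RMSE = %.*f (divisor n)\n",
              digits, x$r_squared, digits, x$rmse))
  invisible(x)
}

#' @export
summary.acceptability_model <- function(object, ...) {
  s <- summary(object$lm)
  cat("Linear acceptability model\n\n")
  print(s$coefficients)
  cat(sprintf("\nR-squared %.4f | RMSE (divisor n) %.4f | n %d\n",
              object$r_squared, object$rmse, object$n))
  invisible(s)
}

#' @export
coef.acceptability_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict acceptability from ratios
#'
#' @param object An `acceptability_model`.
#' @param ratio Numeric vector of sweetening-power/citric-acid ratios; if
#'   omitted, the in-sample fitted values are returned.
#' @param ... Unused.
#' @return Numeric vector of predicted acceptability scores.
#' @export
predict.acceptability_model <- function(object, ratio = NULL, ...) {
  if (is.null(ratio)) return(object$fitted_values)
  object$intercept + object$slope * ratio
}

#' @export
residuals.acceptability_model <- function(object, ...) object$residuals

#' @export
fitted.acceptability_model <- function(object, ...) object$fitted_values

#' @export
plot.acceptability_model <- function(x, ...) {
  d <- x$data
  graphics::plot(d$mean_ratio, d$acceptability,
                 xlab = "sweetening power / citric acid",
                 ylab = "acceptability", pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return A number in `[0, 1]`.
#' @export
squared_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("'x' and 'y' must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("zero variance")
  stats::cor(x, y)^2
}

#' Cross-instrument equivalence report
#'
#' Given variety tables measured on two instruments (same varieties, same
#' acceptability scores), reports the squared correlation of the two ratio
#' columns, both fitted acceptability models, and the squared correlation of
#' their fitted values — the three quantities that establish whether the two
#' instruments support equivalent assays.
#'
#' @param varieties_a,varieties_b Data frames with `variety_id`,
#'   `acceptability` and `mean_ratio`.
#' @return An object of class `instrument_comparison`: list with
#'   `ratio_r_squared`, `model_a`, `model_b`, `prediction_r_squared` and the
#'   merged data.
#' @export
compare_instruments <- function(varieties_a, varieties_b) {
  stopifnot(is.data.frame(varieties_a), is.data.frame(varieties_b))
  need <- c("variety_id", "acceptability", "mean_ratio")
  stopifnot(all(need %in% names(varieties_a)), all(need %in% names(varieties_b)))
  if (!setequal(varieties_a$variety_id, varieties_b$variety_id) ||
      nrow(varieties_a) != nrow(varieties_b))
    stopf("the two instruments must cover the same varieties")
  b <- varieties_b[match(varieties_a$variety_id, varieties_b$variety_id), ]
  ma <- fit_acceptability_model(varieties_a)
  mb <- fit_acceptability_model(b)
  structure(
    list(ratio_r_squared = squared_correlation(varieties_a$mean_ratio, b$mean_ratio),
         model_a = ma, model_b = mb,
         prediction_r_squared = squared_correlation(ma$fitted_values, mb$fitted_values),
         data = data.frame(variety_id = varieties_a$variety_id,
                           acceptability = varieties_a$acceptability,
                           ratio_a = varieties_a$mean_ratio,
                           ratio_b = b$mean_ratio,
                           predicted_a = ma$fitted_values,
                           predicted_b = mb$fitted_values)),
    class = "instrument_comparison"
  )
}

#' @export
print.instrument_comparison <- function(x, ...) {
  cat("Cross-instrument equivalence\n")
  cat(sprintf("  ratio R-squared:      %.4f\n", x$ratio_r_squared))
  cat(sprintf("  prediction R-squared: %.4f\n", x$prediction_r_squared))
  cat(sprintf("  model A: slope %.3f, intercept %.3f, R2 %.3f, RMSE %.3f\n",
              x$model_a$slope, x$model_a$intercept, x$model_a$r_squared,
              x$model_a$rmse))
  cat(sprintf("  model B: slope %.3f, intercept %.3f, R2 %.3f, RMSE %.3f\n",
              x$model_b$slope, x$model_b$intercept, x$model_b$r_squared,
              x$model_b$rmse))
  invisible(x)
}

#' Reference variety table bundled with the package
#'
#' Five mandarin varieties with their consumer-panel acceptability scores and
#' the variety-mean sweetening-power/citric-acid ratios measured on a benchtop
#' (60 MHz) and a high-field (400 MHz) instrument (each ratio the mean of 5
#' replicate extracts). This is the table the worked examples and the
#' equivalence demonstrations are built on.
#'
#' @return Data frame with columns `variety_id`, `acceptability`, `ratio_60`
#'   and `ratio_400`.
#' @export
mandarin_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "citrusnmr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
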