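#' Ground-truth composition of a simulated extract
#'
#' Holds the analyte amounts (arbitrary concentration units) of one simulated
#' aqueous mandarin extract together with the anomeric/tautomeric equilibrium
#' fractions and two nuisance parameters: a per-sample chemical-shift jitter
#' (mimicking referencing error before the 5.22 ppm referencing step) and a
#' citrate centre offset (mimicking the temperature/pH dependence of the
#' citrate methylene shift).
#'
#' @param sucrose,glucose_total,fructose_total,citric_acid Amounts (>= 0,
#'   arbitrary units). Glucose and fructose are totals over their
#'   anomeric/tautomeric forms.
#' @param alpha_glucose_fraction Fraction of glucose present as the alpha
#'   anomer (default 0.36, the aqueous equilibrium value; the beta anomer gets
#'   the complement).
#' @param beta_furanose_fructose_fraction Fraction of fructose present as the
#'   beta-furanose tautomer carrying the 4.09 ppm marker (default 0.25).
#' @param hdo Residual HDO amount (1-proton units). Samples lyophilised and
#'   redissolved in 99.9% D D2O retain a modest residual water line; the
#'   default is comparable to the sucrose anomeric signal.
#' @param shift_jitter_scale Standard deviation (ppm) of the per-sample global
#'   shift applied to every resonance before processing.
#' @param citrate_center_offset Shift (ppm) added to the citrate pattern
#'   centre only. See [default_citrate_offset()].
#' @return An object of class `extract_composition`.
#' @export
extract_composition <- function(sucrose, glucose_total, fructose_total,
                                citric_acid,
                                alpha_glucose_fraction = 0.36,
                                beta_furanose_fructose_fraction = 0.25,
                                hdo = 1.0,
                                shift_jitter_scale = 0,
                                citrate_center_offset = 0) {
  amounts <- c(sucrose = sucrose, glucose_total = glucose_total,
               fructose_total = fructose_total, citric_acid = citric_acid,
               hdo = hdo)
  if (!all(vapply(amounts, is_scalar_num, logical(1))) || any(amounts < 0))
    stopf("all amounts must be finite and >= 0")
  for (f in c(alpha_glucose_fraction, beta_furanose_fructose_fraction))
    if (!is_scalar_num(f) || f < 0 || f > 1)
      stopf("fractions must lie in [0, 1]")
  if (!is_scalar_num(shift_jitter_scale) || shift_jitter_scale < 0)
    stopf("'shift_jitter_scale' must be >= 0 ppm")
  if (!is_scalar_num(citrate_center_offset))
    stopf("'citrate_center_offset' must be a ppm value")
  structure(
    list(sucrose = sucrose, glucose_total = glucose_total,
         fructose_total = fructose_total, citric_acid = citric_acid,
         alpha_glucose_fraction = alpha_glucose_fraction,
         beta_furanose_fructose_fraction = beta_furanose_fructose_fraction,
         hdo = hdo,
         shift_jitter_scale = shift_jitter_scale,
         citrate_center_offset = citrate_center_offset),
    class = "extract_composition"
  )
}

#' Build a composition that targets a given sweetness/acid ratio
#'
#' Mandarin ripening mostly moves the sweetening-power/citric-acid ratio by
#' lowering acidity, so the generator keeps a fixed, mandarin-like sugar
#' profile (glucose and fructose each about half the sucrose level on a molar
#' basis) and sets the citric acid amount so that the noiseless Eq.-style
#' ratio of the true relative areas equals `target_ratio`.
#'
#' @param target_ratio Desired sweetening-power/citric-acid ratio (> 0).
#' @param sugar_level Overall scaling of all sugar amounts (sucrose = 1 at
#'   `sugar_level = 1`).
#' @param weights Sweetness weights used to translate the target ratio into a
#'   citric acid amount; see [sweetness_weights()].
#' @param ... Passed on to [extract_composition()] (fractions, jitter,
#'   citrate offset, ...).
#' @return An `extract_composition`.
#' @export
composition_from_ratio <- function(target_ratio, sugar_level = 1,
                                   weights = sweetness_weights(),
                                   shift_jitter_scale = 0.003, ...) {
  if (!is_scalar_num(target_ratio) || target_ratio <= 0)
    stopf("'target_ratio' must be > 0")
  suc <- 1 * sugar_level
  glc <- 0.507 * sugar_level
  fru <- 0.507 * sugar_level
  tmp <- extract_composition(suc, glc, fru, citric_acid = 1,
                             shift_jitter_scale = shift_jitter_scale, ...)
  ta <- true_relative_areas(tmp)
  sp <- weights$sucrose * ta[["sucrose"]] +
    weights$glucose * (ta[["alpha_glucose"]] + ta[["beta_glucose"]]) +
    weights$fructose * ta[["fructose"]]
  # citrate relative area is 4 * citric / sucrose (4 methylene protons)
  citric <- sp * suc / (4 * target_ratio)
  extract_composition(suc, glc, fru, citric,
                      shift_jitter_scale = shift_jitter_scale, ...)
}

#' Noise-free relative marker areas implied by a composition
#'
#' The areas the five marker windows would report for an ideal instrument with
#' complete capture: each marker's `amount * proton_count * species_fraction`
#' scaled so sucrose is exactly 1. Useful as a recovery target for the
#' simulated pipeline.
#'
#' @param composition An [extract_composition()].
#' @return Named numeric vector (`sucrose`, `alpha_glucose`, `beta_glucose`,
#'   `fructose`, `citrate`).
#' @export
true_relative_areas <- function(composition) {
  stopifnot(inherits(composition, "extract_composition"))
  comp <- composition
  if (comp$sucrose <= 0) stopf("sucrose amount must be > 0 to anchor areas")
  c(sucrose = 1,
    alpha_glucose = comp$alpha_glucose_fraction * comp$glucose_total / comp$sucrose,
    beta_glucose = (1 - comp$alpha_glucose_fraction) * comp$glucose_total / comp$sucrose,
    fructose = 2 * comp$beta_furanose_fructose_fraction * comp$fructose_total / comp$sucrose,
    citrate = 4 * comp$citric_acid / comp$sucrose)
}

#' Default citrate-centre offset for an acquisition scheme
#'
#' The citrate methylene shift moves with temperature and pH; benchtop runs at
#' room temperature place it about 0.2 ppm upfield of its 298 K high-field
#' position, which is also where the benchtop integration window of
#' [default_windows()] expects it.
#'
#' @param scheme An [acquisition_scheme()].
#' @return A ppm offset (0 for high-field, -0.20 for benchtop).
#' @export
default_citrate_offset <- function(scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (identical(scheme$field_tag, "benchtop")) -0.20 else 0
}

#' @export
print.extract_composition <- function(x, ...) {
  cat(sprintf(
    "<extract_composition> suc %.3g, glc %.3g, fru %.3g, citric %.3g (alpha-glc %.2f, beta-fur %.2f)\n",
    x$sucrose, x$glucose_total, x$fructose_total, x$citric_acid,
    x$alpha_glucose_fraction, x$beta_furanose_fructose_fraction))
  invisible(x)
}
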