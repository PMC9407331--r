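#' Reference variety design for simulation studies
#'
#' The five mandarin varieties of the reference assay with their high-field
#' sweetening-power/citric-acid ratios used as simulation targets, so that
#' simulated cohorts span the realistic ratio range (about 4 to 10).
#'
#' @return Data frame with `variety_id` and `target_ratio`.
#' @export
reference_varieties <- function() {
  t1 <- mandarin_table1()
  data.frame(variety_id = t1$variety_id, target_ratio = t1$ratio_400)
}

#' Processing parameters used for simulation studies
#'
#' The default chain with fixed zero phases: FIDs synthesised by
#' [synthesize_fid()] are in absorption phase by construction, so
#' `list(ph0 = 0, ph1 = 0)` is exact for them and keeps large Monte-Carlo
#' studies fast and free of phasing noise. All other settings are the
#' package defaults.
#'
#' @return A [processing_params()] object.
#' @export
simulation_processing_params <- function() {
  processing_params(phase_mode = list(ph0 = 0, ph1 = 0))
}

#' Per-variety replicate RSD of the ratio for one simulated cohort
#'
#' Runs the full chain — simulate, process, align, quantify, score — on one
#' replicate cohort and reports the per-variety mean ratio and relative
#' standard deviation, the quantity whose assay tolerance is an RSD below
#' 20% for every variety.
#'
#' @param seed Integer seed for the cohort.
#' @param varieties Variety design (default [reference_varieties()]).
#' @param n_replicates Replicates per variety (default 5).
#' @param scheme An [acquisition_scheme()].
#' @param replicate_cv,noise_sd Generator settings (defaults as in
#'   [simulate_cohort()]).
#' @param params Processing settings (default
#'   [simulation_processing_params()]).
#' @param weights A [sweetness_weights()].
#' @return Data frame from [aggregate_varieties()]: `variety_id`,
#'   `mean_ratio`, `rsd_percent`, `n_rep`.
#' @export
cohort_ratio_rsd <- function(seed,
                             varieties = reference_varieties(),
                             n_replicates = 5L,
                             scheme = scheme_high_field(),
                             replicate_cv = 0.08,
                             noise_sd = default_noise_sd(scheme),
                             params = simulation_processing_params(),
                             weights = sweetness_weights()) {
  fids <- simulate_cohort(varieties, n_replicates = n_replicates,
                          scheme = scheme, replicate_cv = replicate_cv,
                          noise_sd = noise_sd, seed = seed)
  specs <- process_cohort(fids, params)
  scored <- score_cohort(specs, default_windows(scheme$field_tag), weights)
  aggregate_varieties(scored)
}

#' Cross-field ratio comparison for a set of compositions
#'
#' Synthesises each composition under both acquisition schemes (with the
#' scheme-appropriate citrate centre), runs the full processing and
#' quantification chain, and returns the paired ratios — the simulation
#' analogue of measuring the same extracts on both instruments.
#'
#' @param target_ratios Ratios the compositions are built for (default
#'   spanning the realistic 4-12 range).
#' @param seed Integer seed (noise and shift jitter).
#' @param params Processing settings (default
#'   [simulation_processing_params()]).
#' @param weights A [sweetness_weights()].
#' @return Data frame with `target_ratio`, `ratio_high_field`,
#'   `ratio_benchtop` and `rel_diff_percent`.
#' @export
field_equivalence_study <- function(target_ratios = c(4, 6, 8, 10, 12),
                                    seed = 1L,
                                    params = simulation_processing_params(),
                                    weights = sweetness_weights()) {
  schemes <- list(high_field = scheme_high_field(),
                  benchtop = scheme_benchtop())
  rows <- lapply(seq_along(target_ratios), function(i) {
    tr <- target_ratios[i]
    comp <- composition_from_ratio(tr)
    r <- vapply(schemes, function(sch) {
      comp$citrate_center_offset <- default_citrate_offset(sch)
      fid <- synthesize_fid(comp, sch, seed = seed + i,
                            sample_id = sprintf("ratio%g_%s", tr, sch$field_tag))
      spec <- process_fid(fid, params)
      ra <- relative_areas(spec, default_windows(sch$field_tag))
      sweetness_acid_ratio(ra, weights)
    }, numeric(1))
    data.frame(target_ratio = tr,
               ratio_high_field = r[["high_field"]],
               ratio_benchtop = r[["benchtop"]],
               rel_diff_percent = 100 * (r[["benchtop"]] - r[["high_field"]]) /
                 r[["high_field"]])
  })
  do.call(rbind, rows)
}
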