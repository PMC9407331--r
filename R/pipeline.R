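#' Load and validate a pipeline configuration
#'
#' The pipeline is driven by one declarative configuration (a YAML file or an
#' equivalent nested list) with blocks: `instruments` (one or two entries,
#' each naming a scheme preset — `high_field` / `benchtop` — or giving the
#' full scheme fields, plus the matching `windows` tag), `processing`
#' (any [processing_params()] field), `weights`, an optional `simulation`
#' block (`varieties` with `variety_id`/`target_ratio`, `n_replicates`,
#' `replicate_cv`, `noise_sd`, `seed`, and an `acceptability_rule` with
#' `slope`/`intercept`/`noise_sd` used to attach panel-like scores to the
#' simulated varieties), or an `acceptability_table` (a CSV with
#' `variety_id`, `acceptability` and per-instrument ratio columns; the
#' keyword `"table1"` loads the bundled reference table).
#'
#' Validation fails before any computation if an instrument's window tag does
#' not match its scheme's field tag, or if a simulation block lacks a seed.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$instruments) && is.null(config$acceptability_table))
    stopf("config needs 'instruments' and/or 'acceptability_table'")
  for (inst in config$instruments) {
    scheme <- resolve_scheme(inst$scheme)
    wtag <- inst$windows %||% scheme$field_tag
    if (!wtag %in% c("high_field", "benchtop"))
      stopf("unknown window set '%s'", wtag)
    if (wtag != scheme$field_tag)
      stopf("validation: instrument '%s' pairs a %s scheme with %s windows",
            inst$name %||% scheme$field_tag, scheme$field_tag, wtag)
  }
  if (!is.null(config$simulation) && is.null(config$simulation$seed))
    stopf("validation: simulation block requires a seed")
  structure(config, class = c("pipeline_config", "list"))
}

#' @noRd
resolve_scheme <- function(x) {
  if (inherits(x, "acquisition_scheme")) return(x)
  if (is.character(x)) {
    return(switch(x, high_field = scheme_high_field(),
                  benchtop = scheme_benchtop(),
                  stopf("unknown scheme preset '%s'", x)))
  }
  do.call(acquisition_scheme, x)
}

#' @noRd
resolve_processing <- function(p) {
  if (is.null(p)) return(processing_params())
  if (!is.null(p$phase_mode) && is.list(p$phase_mode))
    p$phase_mode <- list(ph0 = p$phase_mode$ph0 %||% 0,
                         ph1 = p$phase_mode$ph1 %||% 0)
  do.call(processing_params, p)
}

#' Run the end-to-end pipeline from a declarative config
#'
#' Executes (optionally) simulate, then process, quantify, score, fit and
#' compare, writing every intermediate table plus a manifest to the output
#' directory. Re-running the same config with the same seed reproduces
#' identical output files.
#'
#' Outputs: `truth_<instrument>.csv` (simulated ground truth),
#' `areas_<instrument>.csv` (per-replicate relative areas and ratios),
#' `varieties_<instrument>.csv` (variety means, RSDs and acceptability),
#' `model_<instrument>.json` (slope, intercept, R-squared, RMSE, n, weights,
#' window set), `comparison.json` (cross-instrument equivalence) and
#' `manifest.json`.
#'
#' @param config A [pipeline_config()], YAML path or list.
#' @param output_dir Overrides the config's `output_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- pipeline_config(config)
  out <- output_dir %||% config$output_dir %||% stopf("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  weights <- do.call(sweetness_weights, config$weights %||% list())
  params <- resolve_processing(config$processing)
  files <- character(0)
  varieties_by_inst <- list()
  stage <- "configure"
  tryCatch({
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      vt <- do.call(rbind, lapply(sim$varieties, as.data.frame))
      accept <- simulated_acceptability(vt, sim)
      for (inst in config$instruments) {
        stage <- "simulate"
        scheme <- resolve_scheme(inst$scheme)
        name <- inst$name %||% scheme$field_tag
        fids <- simulate_cohort(
          vt, n_replicates = sim$n_replicates %||% 5L, scheme = scheme,
          replicate_cv = sim$replicate_cv %||% 0.08,
          noise_sd = sim$noise_sd %||% default_noise_sd(scheme),
          seed = sim$seed)
        f <- file.path(out, sprintf("truth_%s.csv", name))
        write_cohort_truth(fids, f); files <- c(files, f)
        stage <- "process"
        specs <- process_cohort(fids, params)
        if (isTRUE(config$write_spectra)) {
          for (s in specs) {
            f <- file.path(out, sprintf("spectrum_%s_%s.tsv", name, s$sample_id))
            write_spectrum(s, f); files <- c(files, f)
          }
        }
        stage <- "quantify"
        windows <- default_windows(inst$windows %||% scheme$field_tag)
        scored <- score_cohort(specs, windows, weights)
        f <- file.path(out, sprintf("areas_%s.csv", name))
        utils::write.csv(scored, f, row.names = FALSE); files <- c(files, f)
        stage <- "score"
        agg <- aggregate_varieties(scored)
        agg <- merge(agg, accept, by = "variety_id", sort = FALSE)
        f <- file.path(out, sprintf("varieties_%s.csv", name))
        utils::write.csv(agg, f, row.names = FALSE); files <- c(files, f)
        varieties_by_inst[[name]] <- agg
      }
    }
    if (!is.null(config$acceptability_table)) {
      stage <- "load_table"
      tab <- if (identical(config$acceptability_table, "table1"))
        mandarin_table1()
      else utils::read.csv(config$acceptability_table)
      ratio_cols <- grep("^ratio_", names(tab), value = TRUE)
      for (rc in ratio_cols) {
        name <- sub("^ratio_", "instrument_", rc)
        varieties_by_inst[[name]] <-
          data.frame(variety_id = tab$variety_id,
                     acceptability = tab$acceptability,
                     mean_ratio = tab[[rc]])
      }
    }
    stage <- "fit"
    models <- lapply(varieties_by_inst, fit_acceptability_model)
    for (name in names(models)) {
      m <- models[[name]]
      f <- file.path(out, sprintf("model_%s.json", name))
      jsonlite::write_json(
        list(instrument = name, slope = m$slope, intercept = m$intercept,
             r_squared = m$r_squared, rmse = m$rmse, n = m$n,
             fitted_values = m$fitted_values,
             weights = unclass(weights)),
        f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
    comparison <- NULL
    if (length(varieties_by_inst) >= 2L) {
      stage <- "compare"
      nms <- names(varieties_by_inst)[1:2]
      comparison <- compare_instruments(varieties_by_inst[[nms[1]]],
                                        varieties_by_inst[[nms[2]]])
      f <- file.path(out, "comparison.json")
      jsonlite::write_json(
        list(instruments = nms,
             ratio_r_squared = comparison$ratio_r_squared,
             prediction_r_squared = comparison$prediction_r_squared),
        f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
    stage <- "manifest"
    cfg_file <- file.path(out, "config_used.yaml")
    yaml::write_yaml(unclass(config), cfg_file)
    manifest <- list(
      package = "citrusnmr",
      version = as.character(utils::packageVersion("citrusnmr")),
      config_md5 = unname(tools::md5sum(cfg_file)),
      seed = config$simulation$seed,
      stages = c("simulate"[!is.null(config$simulation)], "process",
                 "quantify", "score", "fit",
                 "compare"[length(varieties_by_inst) >= 2L]),
      files = basename(c(cfg_file, files)))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(manifest = manifest, models = models,
                   comparison = comparison,
                   varieties = varieties_by_inst))
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' @noRd
simulated_acceptability <- function(vt, sim) {
  rule <- sim$acceptability_rule %||%
    list(slope = 0.6, intercept = 1.0, noise_sd = 0.25)
  with_seed(sim$seed + 1L, {
    data.frame(
      variety_id = as.character(vt$variety_id),
      acceptability = rule$intercept + rule$slope * vt$target_ratio +
        stats::rnorm(nrow(vt), 0, rule$noise_sd %||% 0))
  })
}

#' One-command reproduction of the reference regression table
#'
#' Runs the bundled `config-table1.yaml` pipeline: fits the 60 MHz and
#' 400 MHz acceptability models from the bundled variety table and writes the
#' cross-instrument comparison.
#'
#' @param output_dir Where to write results.
#' @return The pipeline manifest, invisibly.
#' @export
repro_table1 <- function(output_dir) {
  cfg <- system.file("extdata", "config-table1.yaml", package = "citrusnmr",
                     mustWork = TRUE)
  run_pipeline(cfg, output_dir = output_dir)
}

#' One-command reproduction of the demonstration figures' data
#'
#' Writes CSVs with the data behind the package's demonstration figures: a
#' field-comparison overlay of one simulated extract at 400 and 60 MHz
#' (`figure_overlay.csv`), the cross-instrument ratio scatter
#' (`figure_ratio_scatter.csv`), the acceptability-vs-ratio scatter with both
#' regression lines (`figure_regression.csv`) and the predicted-vs-predicted
#' scatter (`figure_predictions.csv`).
#'
#' @param output_dir Where to write results.
#' @param seed Seed for the overlay simulation.
#' @return Invisibly, the vector of files written.
#' @export
repro_figures <- function(output_dir, seed = 1L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  comp <- composition_from_ratio(8)
  rows <- list()
  for (scheme in list(scheme_high_field(), scheme_benchtop())) {
    comp$citrate_center_offset <- default_citrate_offset(scheme)
    fid <- synthesize_fid(comp, scheme, seed = seed,
                          sample_id = scheme$field_tag)
    spec <- process_fid(fid)
    keep <- spec$ppm <= 6 & spec$ppm >= 2
    rows[[scheme$field_tag]] <- data.frame(
      instrument = scheme$field_tag, ppm = spec$ppm[keep],
      intensity = spec$real[keep] / max(spec$real[keep]))
  }
  f <- file.path(output_dir, "figure_overlay.csv")
  utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
  files <- c(files, f)

  t1 <- mandarin_table1()
  m60 <- fit_acceptability_model(t1$ratio_60, t1$acceptability)
  m400 <- fit_acceptability_model(t1$ratio_400, t1$acceptability)
  f <- file.path(output_dir, "figure_ratio_scatter.csv")
  utils::write.csv(data.frame(variety_id = t1$variety_id,
                              ratio_400 = t1$ratio_400,
                              ratio_60 = t1$ratio_60), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(output_dir, "figure_regression.csv")
  utils::write.csv(data.frame(variety_id = t1$variety_id,
                              acceptability = t1$acceptability,
                              ratio_400 = t1$ratio_400,
                              fitted_400 = m400$fitted_values,
                              ratio_60 = t1$ratio_60,
                              fitted_60 = m60$fitted_values),
                   f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(output_dir, "figure_predictions.csv")
  utils::write.csv(data.frame(variety_id = t1$variety_id,
                              predicted_400 = m400$fitted_values,
                              predicted_60 = m60$fitted_values),
                   f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
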