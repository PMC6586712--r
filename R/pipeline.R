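# End-to-end orchestration ---------------------------------------------------

#' Full pipeline configuration
#'
#' Bundles the generator configuration, the threshold matrix, the variance
#' method and the forest configuration under a single seed that propagates
#' to every stochastic stage.
#'
#' @param sim a [sim_config()].
#' @param thresholds an [nnpi_thresholds()].
#' @param variance `"local"` or `"srs"`.
#' @param forest a [forest_config()].
#' @param seed master seed; overrides the seeds inside `sim` and `forest`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), thresholds = nnpi_thresholds(),
                       variance = c("local", "srs"),
                       forest = forest_config(), seed = 1L) {
  variance <- match.arg(variance)
  stopifnot(inherits(sim, "sim_config"), inherits(forest, "forest_config"),
            inherits(thresholds, "nnpi_thresholds"))
  sim$seed <- as.integer(seed)
  forest$seed <- as.integer(seed) + 1L
  structure(list(sim = sim, thresholds = thresholds, variance = variance,
                 forest = forest, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the whole pipeline on a synthetic survey
#'
#' Generates a dataset, computes site metrics, classifies sites, estimates
#' area extent per stressor category (nationally, by ecoregion and by
#' wetland type), population-weighted means of the headline metrics,
#' signal-to-noise for the three component metrics, scores the disturbance
#' table, and fits the balanced random forest. When `out_dir` is given every
#' stage output is written as CSV (reports as JSON) along with a manifest
#' recording seed and configuration.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ds <- generate_dataset(config$sim)
  stopifnot(nrow(validate_dataset(ds)) == 0)
  metrics <- site_metrics(ds)
  nnpi <- classify_nnpi(metrics, config$thresholds)

  extent <- do.call(rbind, lapply(c("national", "ecoregion", "wetland_type"),
    function(by) category_extent(ds$sites, nnpi, by = by,
                                 variance = config$variance)))
  m1 <- metrics[match(paste(ds$sites$site_id, ds$sites$visit_no),
                      paste(metrics$site_id, metrics$visit_no)), ]
  popmeans <- do.call(rbind, lapply(
    c("nn_rel_cover", "nn_richness", "nn_rel_freq", "wetland_index",
      "native_richness", "bareground"),
    function(met) population_mean(m1[[met]], ds$sites, by = "ecoregion",
                                  variance = config$variance, metric = met)))
  sn <- lapply(c("nn_richness", "nn_rel_freq", "nn_rel_cover"),
               function(met) {
    v <- data.frame(site_id = metrics$site_id, visit_no = metrics$visit_no,
                    value = metrics[[met]])
    signal_to_noise(v, metric = met)
  })
  sn_df <- do.call(rbind, lapply(sn, function(s)
    data.frame(metric = s$metric, signal_var = s$signal_var,
               noise_var = s$noise_var, ratio = s$ratio,
               n_sites = s$n_sites, n_pairs = s$n_pairs)))

  scored <- score_disturbance(ds$disturbance)
  rf_in <- build_rf_predictors(metrics, nnpi, scored, ds$sites)
  fit <- NULL
  rf_report <- NULL
  if (nlevels(droplevels(rf_in$labels)) == 2 &&
      all(table(rf_in$labels) >= 2)) {
    fit <- fit_balanced_forest(rf_in$predictors, rf_in$labels, config$forest)
    perf <- oob_performance(fit$votes, fit$labels)
    rf_report <- list(pcc_all = perf$pcc_all, pcc_lm = perf$pcc_lm,
                      pcc_hvh = perf$pcc_hvh,
                      importance = as.list(permutation_importance(fit)))
  }
  occurrence <- species_occurrence_table(ds)

  result <- list(dataset = ds, metrics = metrics, nnpi = nnpi,
                 extent = extent, popmeans = popmeans, sn = sn_df,
                 disturbance = scored, occurrence = occurrence,
                 forest = fit, rf_report = rf_report, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(ds, file.path(out_dir, "data"))
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                          row.names = FALSE)
    w(metrics, "site_metrics.csv")
    w(nnpi, "nnpi.csv")
    w(extent, "extent.csv")
    w(popmeans, "popmeans.csv")
    w(sn_df, "signal_to_noise.csv")
    w(scored, "disturbance_scored.csv")
    w(occurrence, "species_table.csv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("nnpi")),
      seed = config$seed, variance = config$variance,
      n_sites = config$sim$n_sites, n_trees = config$forest$n_trees,
      thresholds = unclass(config$thresholds))
    if (!is.null(rf_report)) manifest$rf <- rf_report[c("pcc_all", "pcc_lm",
                                                        "pcc_hvh")]
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
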