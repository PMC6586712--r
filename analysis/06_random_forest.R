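#!/usr/bin/env Rscript
# Stage 6 — class-balanced random-forest exploration of stressor predictors.
#
# Predicts the combined stressor class (LM vs HVH) from the site-level
# vegetation/environment metrics, the overall disturbance index, ecoregion
# and wetland type. 1000 trees, mtry = floor(sqrt(p)), each tree grown on a
# balanced bootstrap the size of the minority class; performance and
# importance are out-of-bag.

suppressMessages(library(nnpi))

out_dir <- "results"
ds <- load_dataset(file.path(out_dir, "data", "cover.csv"),
                   file.path(out_dir, "data", "traits.csv"),
                   file.path(out_dir, "data", "sites.csv"),
                   file.path(out_dir, "data", "disturbance.csv"))
metrics <- read.csv(file.path(out_dir, "site_metrics.csv"))
cls <- read.csv(file.path(out_dir, "nnpi.csv"))
scored <- read.csv(file.path(out_dir, "disturbance_scored.csv"))

rf_in <- build_rf_predictors(metrics, cls, scored, ds$sites)
message(sprintf("modeling %d sites: %s", length(rf_in$labels),
                paste(sprintf("%s = %d", names(table(rf_in$labels)),
                              table(rf_in$labels)), collapse = ", ")))

fit <- fit_balanced_forest(rf_in$predictors, rf_in$labels,
                           forest_config(n_trees = 1000, seed = 102))
perf <- oob_performance(fit$votes, fit$labels)
message(sprintf("OOB percent correctly classified: all %.0f%%, LM %.0f%%, HVH %.0f%%",
                perf$pcc_all, perf$pcc_lm, perf$pcc_hvh))

imp <- permutation_importance(fit)
imp_df <- data.frame(predictor = names(imp), mean_decrease_accuracy = imp,
                     row.names = NULL)
write.csv(imp_df, file.path(out_dir, "rf_importance.csv"), row.names = FALSE)
message("variable importance (mean decrease in accuracy), top 5:")
for (i in 1:5) message(sprintf("  %-24s %.4f", imp_df$predictor[i],
                               imp_df$mean_decrease_accuracy[i]))

# partial dependence for the three most important numeric predictors
num_preds <- names(Filter(is.numeric, rf_in$predictors))
top_num <- head(imp_df$predictor[imp_df$predictor %in% num_preds], 3)
pd <- do.call(rbind, lapply(top_num, function(p) {
  cbind(predictor = p, partial_dependence(fit, p))
}))
write.csv(pd, file.path(out_dir, "rf_partial_dependence.csv"),
          row.names = FALSE)

jsonlite::write_json(
  list(n_sites = length(rf_in$labels), n_trees = fit$config$n_trees,
       mtry = fit$model$mtry, sampsize_per_class = fit$sampsize,
       pcc_all = perf$pcc_all, pcc_lm = perf$pcc_lm, pcc_hvh = perf$pcc_hvh,
       importance = as.list(imp)),
  file.path(out_dir, "rf_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote rf_importance.csv, rf_partial_dependence.csv, rf_report.json")
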