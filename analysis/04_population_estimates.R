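#!/usr/bin/env Rscript
# Stage 4 — design-based population inference.
#
# Horvitz-Thompson area extent per stressor category (national, by
# ecoregion, by wetland type) with local-neighborhood variance 95% CIs;
# population-weighted means of the headline metrics by ecoregion; and
# signal-to-noise repeatability of the three component metrics from the
# revisit pairs.

suppressMessages(library(nnpi))

out_dir <- "results"
ds <- load_dataset(file.path(out_dir, "data", "cover.csv"),
                   file.path(out_dir, "data", "traits.csv"),
                   file.path(out_dir, "data", "sites.csv"),
                   file.path(out_dir, "data", "disturbance.csv"))
metrics <- read.csv(file.path(out_dir, "site_metrics.csv"))
cls <- read.csv(file.path(out_dir, "nnpi.csv"))

extent <- do.call(rbind, lapply(c("national", "ecoregion", "wetland_type"),
  function(by) category_extent(ds$sites, cls, by = by, variance = "local")))
write.csv(extent, file.path(out_dir, "extent.csv"), row.names = FALSE)

nat <- extent[extent$domain == "national", ]
message("national wetland-area extent by stressor level:")
for (i in seq_len(nrow(nat))) {
  message(sprintf("  %-9s %8.0f ha (%4.1f%%)  95%% CI [%.0f, %.0f]",
                  nat$category[i], nat$area_ha[i], nat$pct_of_domain[i],
                  nat$lo[i], nat$hi[i]))
}
hvh_pct <- sum(nat$pct_of_domain[nat$category %in% c("high", "very_high")])
message(sprintf("high + very high: %.1f%% of the estimated wetland area",
                hvh_pct))

aligned <- metrics[match(paste(ds$sites$site_id, ds$sites$visit_no),
                         paste(metrics$site_id, metrics$visit_no)), ]
popmeans <- do.call(rbind, lapply(
  c("nn_rel_cover", "nn_richness", "nn_rel_freq", "wetland_index",
    "native_richness", "bareground"),
  function(met) population_mean(aligned[[met]], ds$sites, by = "ecoregion",
                                variance = "local", metric = met)))
write.csv(popmeans, file.path(out_dir, "popmeans.csv"), row.names = FALSE)
message(sprintf("wrote %d population-weighted subpopulation means",
                nrow(popmeans)))

sn_rows <- lapply(c("nn_richness", "nn_rel_freq", "nn_rel_cover"),
                  function(met) {
  sn <- signal_to_noise(
    data.frame(site_id = metrics$site_id, visit_no = metrics$visit_no,
               value = metrics[[met]]), metric = met)
  data.frame(metric = met, signal_var = sn$signal_var,
             noise_var = sn$noise_var, ratio = sn$ratio,
             n_pairs = sn$n_pairs)
})
sn_df <- do.call(rbind, sn_rows)
write.csv(sn_df, file.path(out_dir, "signal_to_noise.csv"), row.names = FALSE)
message("signal-to-noise (values above 2 indicate a usable metric):")
for (i in seq_len(nrow(sn_df))) {
  message(sprintf("  %-13s S:N = %s", sn_df$metric[i],
                  formatC(sn_df$ratio[i], digits = 3)))
}
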