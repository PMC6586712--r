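#!/usr/bin/env Rscript
# Stage 2 — per-site vegetation metrics and the nonnative occurrence table.
#
# Computes, for every site visit, the three nonnative component metrics
# (relative cover, richness, relative frequency), native richness, the
# cover-weighted wetland index, and absolute cover by growth habit; plus the
# cross-site occurrence table of nonnative taxa.

suppressMessages(library(nnpi))

out_dir <- "results"
ds <- load_dataset(file.path(out_dir, "data", "cover.csv"),
                   file.path(out_dir, "data", "traits.csv"),
                   file.path(out_dir, "data", "sites.csv"),
                   file.path(out_dir, "data", "disturbance.csv"))

metrics <- site_metrics(ds)
write.csv(metrics, file.path(out_dir, "site_metrics.csv"), row.names = FALSE)

occ <- species_occurrence_table(ds)
write.csv(occ, file.path(out_dir, "species_table.csv"), row.names = FALSE)

message(sprintf("metrics for %d site-visits", nrow(metrics)))
message(sprintf("nonnative relative cover: median %.1f%%, range %.1f-%.1f%%",
                median(metrics$nn_rel_cover), min(metrics$nn_rel_cover),
                max(metrics$nn_rel_cover)))
message(sprintf("wetland index range: %.2f-%.2f",
                min(metrics$wetland_index, na.rm = TRUE),
                max(metrics$wetland_index, na.rm = TRUE)))
message(sprintf("%d nonnative taxa observed; most widespread at %d sites",
                nrow(occ), max(occ$n_sites)))
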