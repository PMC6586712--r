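#!/usr/bin/env Rscript
# Stage 3 — stressor-level classification via the max-filter decision matrix.
#
# Each site visit's three component metrics are bracketed against the default
# exceedance thresholds (relative cover 1/15/40, richness 5/10/15, relative
# frequency 10/30/60); the site takes the highest per-metric level.

suppressMessages(library(nnpi))

out_dir <- "results"
metrics <- read.csv(file.path(out_dir, "site_metrics.csv"))

cls <- classify_nnpi(metrics, nnpi_thresholds())
write.csv(cls, file.path(out_dir, "nnpi.csv"), row.names = FALSE)

v1 <- cls[cls$visit_no == 1, ]
tab <- table(v1$overall)
message("site counts by stressor level (first visits):")
for (lv in names(tab)) message(sprintf("  %-9s %4d (%.1f%%)", lv, tab[[lv]],
                                       100 * tab[[lv]] / nrow(v1)))
ctab <- table(v1$combined)
message(sprintf("combined classes: LM %d (%.0f%%) vs HVH %d (%.0f%%)",
                ctab[["LM"]], 100 * ctab[["LM"]] / nrow(v1),
                ctab[["HVH"]], 100 * ctab[["HVH"]] / nrow(v1)))
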