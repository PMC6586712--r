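#!/usr/bin/env Rscript
# Stage 5 — composite site-level human-disturbance index.
#
# Standardizes the eight raw disturbance sub-indices to 0-10 by min-max over
# all sampled sites, combines them into the 0-100 overall index, and
# contrasts it across the combined stressor classes.

suppressMessages(library(nnpi))

out_dir <- "results"
dist_raw <- read.csv(file.path(out_dir, "data", "disturbance.csv"))
cls <- read.csv(file.path(out_dir, "nnpi.csv"))

scored <- score_disturbance(dist_raw)
write.csv(scored, file.path(out_dir, "disturbance_scored.csv"),
          row.names = FALSE)

v1 <- cls[cls$visit_no == 1, ]
ov <- scored$overall[match(v1$site_id, scored$site_id)]
message(sprintf("overall disturbance index: median %.1f, IQR %.1f-%.1f",
                median(ov), quantile(ov, 0.25), quantile(ov, 0.75)))
for (cc in c("LM", "HVH")) {
  message(sprintf("  mean index at %s sites: %.1f", cc,
                  mean(ov[v1$combined == cc])))
}
message(sprintf("correlation with nonnative relative cover: %.2f",
                cor(ov, v1$nn_rel_cover)))
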