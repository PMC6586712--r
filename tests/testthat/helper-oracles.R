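# Independent brute-force oracles, kept deliberately separate from the
# package's staged computations.

# Metrics computed by direct summation over the raw plot table of one site
# visit: relative cover reduces to the ratio of raw cover sums; relative
# frequency to the ratio of distinct (taxon, plot) occurrence counts.
oracle_site_metrics <- function(cov, traits, n_plots) {
  if (nrow(cov) == 0) {
    return(list(nn_richness = 0L, nn_rel_freq = 0, nn_rel_cover = 0,
                wetland_index = NA_real_))
  }
  status <- traits$native_status[match(cov$taxon_id, traits$taxon_id)]
  nn_row <- status %in% c("INTRODUCED", "ADVENTIVE", "CRYPTOGENIC")
  occ <- unique(cov[c("taxon_id", "plot_id")])
  occ_nn <- occ$taxon_id %in% unique(cov$taxon_id[nn_row])
  wis <- traits$wis[match(cov$taxon_id, traits$taxon_id)]
  has_wis <- !is.na(wis)
  list(
    nn_richness = length(unique(cov$taxon_id[nn_row])),
    nn_rel_freq = sum(occ_nn) / nrow(occ) * 100,
    nn_rel_cover = sum(cov$cover[nn_row]) / sum(cov$cover) * 100,
    wetland_index = if (any(has_wis)) {
      sum(cov$cover[has_wis] * wis[has_wis]) / sum(cov$cover[has_wis])
    } else NA_real_)
}

# Explicit three-way bracket classifier written independently of
# level_for_metric: plain if/else chains per metric, then the max filter.
oracle_classify <- function(richness, freq, cover) {
  bracket <- function(v, c1, c2, c3) {
    if (v <= c1) 1L else if (v <= c2) 2L else if (v <= c3) 3L else 4L
  }
  lv <- max(bracket(cover, 1, 15, 40),
            bracket(richness, 5, 10, 15),
            bracket(freq, 10, 30, 60))
  c("low", "moderate", "high", "very_high")[lv]
}
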