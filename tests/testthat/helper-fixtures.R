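# Tiny in-code fixtures shared across test files

toy_traits <- function() {
  data.frame(
    taxon_id = c("NAT1", "NAT2", "NON1", "NON2", "UND1"),
    native_status = c("NATIVE", "NATIVE", "INTRODUCED", "CRYPTOGENIC",
                      "UNDETERMINED"),
    growth_habit = c("FORB", "TREE", "FORB", "GRAMINOID", "SHRUB"),
    wis = c(1L, 5L, 3L, 4L, NA),
    stringsAsFactors = FALSE)
}

toy_sites <- function(n = 2) {
  data.frame(
    site_id = sprintf("S%02d", seq_len(n)), visit_no = 1L,
    x = seq_len(n) / n, y = rev(seq_len(n)) / n,
    weight = seq_len(n) * 10,
    ecoregion = rep_len(c("CPL", "XER"), n),
    wetland_type = rep_len(c("PRLH", "EH"), n),
    is_probability = TRUE, bareground = 5,
    stringsAsFactors = FALSE)
}

toy_cover <- function() {
  # S01: NAT1 in plots 1-5 at 10; NON1 in plot 1 at 50
  data.frame(
    site_id = c(rep("S01", 6), "S02"),
    visit_no = 1L,
    plot_id = c(1:5, 1L, 1L),
    taxon_id = c(rep("NAT1", 5), "NON1", "NAT2"),
    cover = c(rep(10, 5), 50, 30),
    stringsAsFactors = FALSE)
}

toy_dataset <- function() {
  as_dataset(toy_cover(), toy_traits(), toy_sites(),
             disturbance = data.frame(site_id = c("S01", "S02"),
                                      matrix(1:16, nrow = 2,
                                             dimnames = list(NULL,
                                               paste0("idx", 1:8)))))
}

# One-site cover table from per-taxon (cover, wis, status) specs; each taxon
# occupies a single plot.
one_site_summaries <- function(covers) {
  data.frame(taxon_id = names(covers),
             freq_pct = 20, site_cover = as.numeric(covers),
             importance = (20 + as.numeric(covers)) / 2,
             stringsAsFactors = FALSE)
}
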