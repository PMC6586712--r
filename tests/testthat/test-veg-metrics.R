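test_that("per-site species summaries follow the plot aggregation rule", {
  cov <- data.frame(site_id = "A", visit_no = 1L,
                    plot_id = c(1:5, 3L), taxon_id = c(rep("X", 5), "Y"),
                    cover = c(rep(10, 5), 50))
  s <- summarize_species_by_site(cov, n_plots = 5)
  sx <- s[s$taxon_id == "X", ]
  sy <- s[s$taxon_id == "Y", ]
  expect_equal(sx$freq_pct, 100)
  expect_equal(sx$site_cover, 10)
  expect_equal(sy$freq_pct, 20)     # 1 of 5 plots
  expect_equal(sy$site_cover, 10)   # 50 / 5
  expect_equal(sy$importance, 15)
  expect_equal(nrow(summarize_species_by_site(cov[0, ], 5)), 0)
  expect_error(summarize_species_by_site(cov, n_plots = 0), "positive")
  expect_error(summarize_species_by_site(cov, n_plots = 4), "beyond")
})

test_that("nonnative metrics follow the relative-share formulas", {
  traits <- toy_traits()
  # one nonnative (freq 100, cover 10) + one native (freq 100, cover 30)
  s <- data.frame(taxon_id = c("NON1", "NAT1"), freq_pct = c(100, 100),
                  site_cover = c(10, 30), importance = c(55, 65))
  m <- nonnative_metrics(s, traits)
  expect_equal(m$nn_richness, 1)
  expect_equal(m$nn_rel_freq, 50)
  expect_equal(m$nn_rel_cover, 25)
  # no nonnatives
  s2 <- s; s2$taxon_id <- c("NAT1", "NAT2")
  expect_equal(unlist(nonnative_metrics(s2, traits), use.names = FALSE),
               c(0, 0, 0))
  # all nonnative: both shares are 100
  s3 <- s; s3$taxon_id <- c("NON1", "NON2")
  m3 <- nonnative_metrics(s3, traits)
  expect_equal(m3$nn_rel_freq, 100)
  expect_equal(m3$nn_rel_cover, 100)
  # empty site: vegetation-free zeros
  expect_equal(nonnative_metrics(s[0, ], traits)$nn_rel_cover, 0)
  # undetermined taxa dilute but never count as nonnative
  s4 <- rbind(s, data.frame(taxon_id = "UND1", freq_pct = 100,
                            site_cover = 40, importance = 70))
  m4 <- nonnative_metrics(s4, traits)
  expect_equal(m4$nn_richness, 1)
  expect_equal(m4$nn_rel_cover, 10 / 80 * 100)
})

test_that("the wetland index is the cover-weighted indicator mean", {
  tr <- data.frame(taxon_id = c("A", "B", "C"),
                   native_status = "NATIVE", growth_habit = "FORB",
                   wis = c(1L, 5L, NA))
  s <- function(ids, covers) {
    data.frame(taxon_id = ids, freq_pct = 50, site_cover = covers,
               importance = (50 + covers) / 2)
  }
  expect_equal(wetland_index(s("A", 30), tr), 1)          # entirely OBL
  expect_equal(wetland_index(s("B", 30), tr), 5)          # entirely UPL
  expect_equal(wetland_index(s(c("A", "B"), c(50, 50)), tr), 3)
  expect_equal(wetland_index(s(c("A", "B"), c(75, 25)), tr), 2)
  # taxa without a status are excluded from both sums
  expect_equal(wetland_index(s(c("A", "C"), c(30, 90)), tr), 1)
  expect_true(is.na(wetland_index(s("C", 10), tr)))
  empty <- data.frame(taxon_id = character(0), freq_pct = numeric(0),
                      site_cover = numeric(0), importance = numeric(0))
  expect_true(is.na(wetland_index(empty, tr)))
})

test_that("growth-habit covers sum members and honor the tree-shrub merge", {
  tr <- data.frame(
    taxon_id = c("F1", "F2", "T1", "S1", "N1"),
    native_status = c("INTRODUCED", "ADVENTIVE", "INTRODUCED", "CRYPTOGENIC",
                      "NATIVE"),
    growth_habit = c("FORB", "FORB", "TREE", "SHRUB", "FORB"),
    wis = NA_integer_)
  s <- data.frame(taxon_id = c("F1", "F2", "T1", "S1", "N1"),
                  freq_pct = 20, site_cover = c(10, 20, 5, 7, 99),
                  importance = 15)
  hc <- growth_habit_cover(s, tr, "NONNATIVE")
  expect_equal(hc[["FORB"]], 30)
  expect_equal(hc[["GRAMINOID"]], 0)
  merged <- growth_habit_cover(s, tr, "NONNATIVE", combine_tree_shrub = TRUE)
  expect_equal(merged[["TREE_SHRUB"]], 12)
  expect_equal(growth_habit_cover(s, tr, "NATIVE")[["FORB"]], 99)
})

test_that("importance values are bounded means of frequency and cover", {
  expect_equal(importance_value(100, 100), 100)
  expect_equal(importance_value(40, 20), 30)
  expect_equal(importance_value(0, 0), 0)
  expect_error(importance_value(120, 10), "\\[0, 100\\]")
  expect_error(importance_value(10, -1), "\\[0, 100\\]")
})

test_that("relative covers of the three status groups sum to 100", {
  ds <- generate_dataset(sim_config(n_sites = 30, seed = 77))
  key <- paste(ds$cover$site_id, ds$cover$visit_no)
  for (k in unique(key)[1:10]) {
    cov <- ds$cover[key == k, ]
    s <- summarize_species_by_site(cov, ds$n_plots)
    status <- ds$traits$native_status[match(s$taxon_id, ds$traits$taxon_id)]
    shares <- tapply(s$site_cover,
                     ifelse(is_nonnative(status), "nn",
                            ifelse(status == "NATIVE", "nat", "und")),
                     sum)
    expect_equal(sum(shares) / sum(s$site_cover) * 100, 100)
    m <- nonnative_metrics(s, ds$traits)
    expect_equal(m$nn_rel_cover,
                 sum(shares["nn"], na.rm = TRUE) / sum(s$site_cover) * 100)
  }
})

test_that("metrics are invariant to row order and agree with the raw-table oracle", {
  ds <- generate_dataset(sim_config(n_sites = 100, seed = 55))
  m <- site_metrics(ds)
  key <- paste(ds$cover$site_id, ds$cover$visit_no)
  for (i in seq_len(nrow(m))) {
    k <- paste(m$site_id[i], m$visit_no[i])
    cov <- ds$cover[key == k, ]
    o <- oracle_site_metrics(cov, ds$traits, ds$n_plots)
    expect_equal(m$nn_richness[i], o$nn_richness)
    expect_equal(m$nn_rel_freq[i], o$nn_rel_freq, tolerance = 1e-9)
    expect_equal(m$nn_rel_cover[i], o$nn_rel_cover, tolerance = 1e-9)
    expect_equal(m$wetland_index[i], o$wetland_index, tolerance = 1e-9)
  }
  # shuffling the plot rows changes nothing
  set.seed(1)
  shuffled <- ds
  shuffled$cover <- ds$cover[sample(nrow(ds$cover)), ]
  expect_equal(site_metrics(shuffled), m, tolerance = 1e-12)
})

test_that("the occurrence table orders nonnative taxa by habit then spread", {
  ds <- generate_dataset(sim_config(n_sites = 40, seed = 9))
  tab <- species_occurrence_table(ds)
  expect_true(all(is_nonnative(
    ds$traits$native_status[match(tab$taxon_id, ds$traits$taxon_id)])))
  expect_true(all(tab$n_sites >= 1))
  # per-ecoregion counts decompose the site count
  eco_cols <- paste0("n_", c("CPL", "EMU", "IPL", "XER", "WMT"))
  expect_equal(rowSums(tab[eco_cols]), tab$n_sites, ignore_attr = TRUE)
  # ordering: habit blocks in habit order, descending n_sites within
  habit_rank <- match(tab$growth_habit,
                      c("FORB", "GRAMINOID", "VINE", "SHRUB", "TREE"))
  expect_true(all(diff(habit_rank) >= 0))
  within_block <- ave(tab$n_sites, tab$growth_habit,
                      FUN = function(v) all(diff(v) <= 0))
  expect_true(all(within_block == 1))
  # mean importance at occurrence: re-derive for the most widespread taxon
  top <- tab$taxon_id[which.max(tab$n_sites)]
  cov1 <- ds$cover[ds$cover$visit_no == 1, ]
  imps <- vapply(split(cov1, cov1$site_id), function(cv) {
    s <- summarize_species_by_site(cv, ds$n_plots)
    if (top %in% s$taxon_id) s$importance[s$taxon_id == top] else NA_real_
  }, numeric(1))
  expect_equal(tab$mean_importance[tab$taxon_id == top],
               mean(imps, na.rm = TRUE))
})
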