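# Per-site vegetation metrics -----------------------------------------------

#' Summarise species occurrence and cover at one site visit
#'
#' Aggregates a site's plot-level cover records to one row per taxon:
#' frequency as the percent of vegetation plots in which the taxon occurred,
#' site-level cover as the mean of per-plot absolute covers over all
#' `n_plots` plots (plots where the taxon is absent contribute 0), and the
#' importance value (frequency + cover)/2.
#'
#' @param cover data.frame of cover records for a single site visit, with
#'   columns `plot_id`, `taxon_id`, `cover`.
#' @param n_plots the fixed number of vegetation plots per site (frequency
#'   and cover denominator).
#' @return data.frame with columns `taxon_id`, `freq_pct`, `site_cover`,
#'   `importance`, one row per distinct taxon (zero rows for an unvegetated
#'   site).
#' @export
summarize_species_by_site <- function(cover, n_plots = 5L) {
  if (!is.numeric(n_plots) || n_plots <= 0) {
    stop("n_plots must be a positive integer", call. = FALSE)
  }
  empty <- data.frame(taxon_id = character(), freq_pct = numeric(),
                      site_cover = numeric(), importance = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(cover) || nrow(cover) == 0) return(empty)
  if (any(cover$plot_id > n_plots)) {
    stop("cover records reference plot_id beyond n_plots", call. = FALSE)
  }
  n_occ <- tapply(cover$plot_id, cover$taxon_id,
                  function(p) length(unique(p)))
  total_cover <- tapply(cover$cover, cover$taxon_id, sum)
  taxa <- names(n_occ)
  freq_pct <- as.numeric(n_occ[taxa]) / n_plots * 100
  site_cover <- as.numeric(total_cover[taxa]) / n_plots
  out <- data.frame(taxon_id = taxa, freq_pct = freq_pct,
                    site_cover = site_cover,
                    importance = importance_value(freq_pct, site_cover),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Importance value of a species at a site
#'
#' The mean of percent frequency and percent cover, `(freq + cover)/2`.
#'
#' @param freq_pct,site_cover numeric vectors in \[0, 100\].
#' @return numeric vector in \[0, 100\].
#' @export
importance_value <- function(freq_pct, site_cover) {
  if (any(freq_pct < 0 | freq_pct > 100, na.rm = TRUE) ||
      any(site_cover < 0 | site_cover > 100, na.rm = TRUE)) {
    stop("frequency and cover must lie in [0, 100]", call. = FALSE)
  }
  (freq_pct + site_cover) / 2
}

join_traits <- function(summaries, traits) {
  idx <- match(summaries$taxon_id, traits$taxon_id)
  if (anyNA(idx)) {
    stop(sprintf("taxa without trait rows: %s",
                 paste(utils::head(summaries$taxon_id[is.na(idx)], 5),
                       collapse = ", ")), call. = FALSE)
  }
  cbind(summaries, traits[idx, setdiff(names(traits), "taxon_id"),
                          drop = FALSE])
}

#' The three nonnative component metrics for one site visit
#'
#' Nonnative richness (count of distinct nonnative taxa), nonnative relative
#' frequency (sum of nonnative frequencies over the sum of all taxa's
#' frequencies, x100) and nonnative relative cover (same ratio on site-level
#' covers). Taxa of undetermined status enter the denominators only. An
#' unvegetated site returns zeros for all three.
#'
#' @param summaries output of [summarize_species_by_site()].
#' @param traits taxon trait table.
#' @return list with `nn_richness`, `nn_rel_freq`, `nn_rel_cover`.
#' @export
nonnative_metrics <- function(summaries, traits) {
  if (nrow(summaries) == 0) {
    return(list(nn_richness = 0L, nn_rel_freq = 0, nn_rel_cover = 0))
  }
  s <- join_traits(summaries, traits)
  nn <- is_nonnative(s$native_status)
  list(nn_richness = sum(nn),
       nn_rel_freq = sum(s$freq_pct[nn]) / sum(s$freq_pct) * 100,
       nn_rel_cover = sum(s$site_cover[nn]) / sum(s$site_cover) * 100)
}

#' Cover-weighted wetland index
#'
#' The mean of numeric wetland indicator statuses (OBL = 1 ... UPL = 5)
#' weighted by site-level absolute cover, over the taxa with a defined
#' status: sum(wis_i * cover_i) / sum(cover_i). A value of 1 indicates
#' entirely obligate-wetland vegetation, 5 entirely upland vegetation.
#'
#' @inheritParams nonnative_metrics
#' @return a number in \[1, 5\], or NA when no taxon has a defined status.
#' @export
wetland_index <- function(summaries, traits) {
  if (nrow(summaries) == 0) return(NA_real_)
  s <- join_traits(summaries, traits)
  s <- s[!is.na(s$wis), , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  sum(s$wis * s$site_cover) / sum(s$site_cover)
}

#' Absolute cover by growth-habit group
#'
#' Sums site-level absolute cover over the taxa in a status group (native or
#' nonnative) for each growth habit. Absolute covers are summable above 100%
#' across taxa. With `combine_tree_shrub = TRUE` trees and shrubs are
#' reported as a single `TREE_SHRUB` group (the convention used for
#' nonnative woody cover).
#'
#' @inheritParams nonnative_metrics
#' @param status_filter `"NATIVE"` or `"NONNATIVE"`.
#' @param combine_tree_shrub merge TREE and SHRUB into one group.
#' @return named numeric vector over the habit groups; groups with no member
#'   taxa report 0.
#' @export
growth_habit_cover <- function(summaries, traits,
                               status_filter = c("NATIVE", "NONNATIVE"),
                               combine_tree_shrub = FALSE) {
  status_filter <- match.arg(status_filter)
  groups <- if (combine_tree_shrub) {
    c("FORB", "GRAMINOID", "VINE", "TREE_SHRUB")
  } else {
    growth_habits
  }
  out <- stats::setNames(numeric(length(groups)), groups)
  if (nrow(summaries) == 0) return(out)
  s <- join_traits(summaries, traits)
  keep <- if (status_filter == "NATIVE") {
    s$native_status == "NATIVE"
  } else {
    is_nonnative(s$native_status)
  }
  s <- s[keep, , drop = FALSE]
  if (nrow(s) == 0) return(out)
  habit <- s$growth_habit
  if (combine_tree_shrub) {
    habit[habit %in% c("TREE", "SHRUB")] <- "TREE_SHRUB"
  }
  sums <- tapply(s$site_cover, habit, sum)
  out[names(sums)] <- as.numeric(sums)
  out
}

#' Compute the full per-site-visit metric table
#'
#' For every site visit in the dataset: the three nonnative component
#' metrics, total and native richness, the wetland index, total summed
#' cover, native absolute cover by growth habit, nonnative absolute cover by
#' habit with trees and shrubs combined, and bareground carried over from
#' the site table.
#'
#' @param ds an `nnpi_dataset`.
#' @return data.frame with one row per site visit (all rows of `ds$sites`
#'   are represented; unvegetated site-visits get zero metrics and NA
#'   wetland index).
#' @export
site_metrics <- function(ds) {
  stopifnot(inherits(ds, "nnpi_dataset"))
  st <- ds$sites
  key <- paste(st$site_id, st$visit_no)
  cov_split <- split(ds$cover, paste(ds$cover$site_id, ds$cover$visit_no))
  rows <- lapply(seq_len(nrow(st)), function(i) {
    cov <- cov_split[[key[i]]]
    summ <- summarize_species_by_site(cov, ds$n_plots)
    nn <- nonnative_metrics(summ, ds$traits)
    s <- if (nrow(summ)) join_traits(summ, ds$traits) else summ
    nat_cov <- growth_habit_cover(summ, ds$traits, "NATIVE")
    non_cov <- growth_habit_cover(summ, ds$traits, "NONNATIVE",
                                  combine_tree_shrub = TRUE)
    data.frame(
      site_id = st$site_id[i], visit_no = st$visit_no[i],
      richness = nrow(summ),
      native_richness = if (nrow(summ)) sum(s$native_status == "NATIVE") else 0L,
      nn_richness = nn$nn_richness,
      nn_rel_freq = nn$nn_rel_freq,
      nn_rel_cover = nn$nn_rel_cover,
      wetland_index = wetland_index(summ, ds$traits),
      total_cover = sum(summ$site_cover),
      native_cover_forb = nat_cov[["FORB"]],
      native_cover_graminoid = nat_cov[["GRAMINOID"]],
      native_cover_vine = nat_cov[["VINE"]],
      native_cover_shrub = nat_cov[["SHRUB"]],
      native_cover_tree = nat_cov[["TREE"]],
      nonnative_cover_forb = non_cov[["FORB"]],
      nonnative_cover_graminoid = non_cov[["GRAMINOID"]],
      nonnative_cover_vine = non_cov[["VINE"]],
      nonnative_cover_tree_shrub = non_cov[["TREE_SHRUB"]],
      bareground = st$bareground[i],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Occurrence table of nonnative taxa across sites
#'
#' Lists every nonnative taxon observed at one or more sites (first visits
#' only) with its growth habit, the number of sites of occurrence, the mean
#' importance value at those sites, and per-ecoregion occurrence counts.
#' Rows are ordered by growth habit, then by descending number of sites.
#'
#' @param ds an `nnpi_dataset`.
#' @return data.frame with columns `taxon_id`, `growth_habit`, `n_sites`,
#'   `mean_importance`, and one `n_<ecoregion>` column per ecoregion.
#' @export
species_occurrence_table <- function(ds) {
  stopifnot(inherits(ds, "nnpi_dataset"))
  st <- ds$sites[ds$sites$visit_no == 1, ]
  cov <- ds$cover[ds$cover$visit_no == 1 & ds$cover$site_id %in% st$site_id, ]
  empty <- data.frame(taxon_id = character(), growth_habit = character(),
                      n_sites = integer(), mean_importance = numeric())
  if (nrow(cov) == 0) return(empty)
  per_site <- lapply(split(cov, cov$site_id), summarize_species_by_site,
                     n_plots = ds$n_plots)
  long <- do.call(rbind, Map(function(s, id) {
    if (nrow(s)) cbind(site_id = id, s) else NULL
  }, per_site, names(per_site)))
  long <- join_traits(long, ds$traits)
  long <- long[is_nonnative(long$native_status), , drop = FALSE]
  if (nrow(long) == 0) return(empty)
  long$ecoregion <- st$ecoregion[match(long$site_id, st$site_id)]
  agg <- lapply(split(long, long$taxon_id), function(d) {
    counts <- table(factor(d$ecoregion, levels = ecoregions))
    row <- data.frame(taxon_id = d$taxon_id[1],
                      growth_habit = d$growth_habit[1],
                      n_sites = nrow(d),
                      mean_importance = mean(d$importance),
                      stringsAsFactors = FALSE)
    for (e in ecoregions) row[[paste0("n_", e)]] <- as.integer(counts[[e]])
    row
  })
  out <- do.call(rbind, agg)
  out <- out[order(match(out$growth_habit, growth_habits), -out$n_sites,
                   out$taxon_id), ]
  rownames(out) <- NULL
  out
}
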