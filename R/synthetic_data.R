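# Synthetic wetland-survey generator ----------------------------------------

#' Configuration of the synthetic survey generator
#'
#' Defaults emulate the structure of a national wetland probability survey:
#' five 100-m2 vegetation plots per site, a species pool with roughly 30%
#' nonnative taxa spanning the five growth habits, log-normal percent
#' covers, unequal gamma-distributed areal weights, ecoregion- and
#' wetland-type-specific nonnative prevalence, about 10% of sites revisited
#' within the season, and eight disturbance sub-indices positively linked
#' to nonnative occupancy.
#'
#' @param n_sites number of distinct sites (first visits).
#' @param n_plots vegetation plots per site.
#' @param seed integer RNG seed; fixes the output exactly.
#' @param species_pool_size size of the regional species pool.
#' @param nonnative_fraction proportion of the pool that is nonnative.
#' @param nonnative_weight baseline selection weight of a nonnative taxon
#'   relative to a native one at an average site; the default 0.35 makes
#'   roughly 72% of sites fall in the combined low-moderate class under the
#'   default thresholds, matching the imbalance typical of national wetland
#'   surveys.
#' @param ecoregion_mult,wetland_type_mult named multipliers of nonnative
#'   prevalence per stratum (their product scales a nonnative taxon's
#'   selection weight at sites of that stratum).
#' @param cover_meanlog,cover_sdlog log-normal parameters of per-plot
#'   percent cover (truncated to (0, 100\]).
#' @param richness_mean Poisson mean of per-site species richness.
#' @param revisit_fraction proportion of sites revisited (visit 2).
#' @param revisit_noise_sd per-measurement SD (percentage points) of the
#'   nonnative relative-cover metric; applied to every site visit, so half
#'   the mean squared revisit difference estimates its square.
#' @param disturbance_effect slope linking the latent site disturbance level
#'   (0-1) to the log selection weight of nonnative taxa; 0 decouples them.
#' @param weight_shape,weight_scale gamma parameters of the areal survey
#'   weights (hectares).
#' @param nonprobability_fraction proportion of sites flagged as
#'   non-probability (excluded from design-based estimation).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 200L, n_plots = 5L, seed = 1L,
                       species_pool_size = 150L, nonnative_fraction = 0.3,
                       nonnative_weight = 0.35,
                       ecoregion_mult = c(CPL = 1, EMU = 0.7, IPL = 1.6,
                                          XER = 1.8, WMT = 0.6),
                       wetland_type_mult = c(EH = 0.8, EW = 0.6, PRLH = 1.2,
                                             PRLW = 1.1),
                       cover_meanlog = 1.2, cover_sdlog = 1.1,
                       richness_mean = 25, revisit_fraction = 0.1,
                       revisit_noise_sd = 2, disturbance_effect = 1.5,
                       weight_shape = 1.2, weight_scale = 400,
                       nonprobability_fraction = 0.15) {
  cfg <- list(n_sites = as.integer(n_sites), n_plots = as.integer(n_plots),
              seed = as.integer(seed),
              species_pool_size = as.integer(species_pool_size),
              nonnative_fraction = nonnative_fraction,
              nonnative_weight = nonnative_weight,
              ecoregion_mult = ecoregion_mult,
              wetland_type_mult = wetland_type_mult,
              cover_meanlog = cover_meanlog, cover_sdlog = cover_sdlog,
              richness_mean = richness_mean,
              revisit_fraction = revisit_fraction,
              revisit_noise_sd = revisit_noise_sd,
              disturbance_effect = disturbance_effect,
              weight_shape = weight_shape, weight_scale = weight_scale,
              nonprobability_fraction = nonprobability_fraction)
  props <- c("nonnative_fraction", "revisit_fraction",
             "nonprobability_fraction")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("%s must lie in [0, 1]", p), call. = FALSE)
    }
  }
  if (cfg$n_sites < 1 || cfg$n_plots < 1 || cfg$species_pool_size < 2) {
    stop("n_sites, n_plots and species_pool_size must be positive",
         call. = FALSE)
  }
  if (cfg$nonnative_fraction == 0 && cfg$disturbance_effect != 0) {
    stop(paste("disturbance_effect != 0 requires a nonzero",
               "nonnative_fraction (no nonnative taxa to respond)"),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

rtrunc_cover <- function(n, meanlog, sdlog) {
  pmin(stats::rlnorm(n, meanlog, sdlog), 100)
}

# Rescale a site-visit's nonnative plot covers so the realized nonnative
# relative cover equals target_pct exactly (up to per-record truncation at
# 100). Returns the cover vector unchanged when the site has no nonnative or
# no other cover.
apply_metric_noise <- function(cover, is_nn, target_pct) {
  c_nn <- sum(cover[is_nn])
  c_other <- sum(cover[!is_nn])
  if (c_nn == 0 || c_other == 0) return(cover)
  target_pct <- min(max(target_pct, 0.01), 99.9)
  f <- target_pct * c_other / ((100 - target_pct) * c_nn)
  cover[is_nn] <- pmin(cover[is_nn] * f, 100)
  cover
}

#' Generate a synthetic survey dataset
#'
#' Draws a species pool, site frame, plot-level covers and disturbance
#' sub-indices per the configuration; see [sim_config()] for the emulated
#' structure. The same configuration (including seed) always yields an
#' identical dataset.
#'
#' @param config a [sim_config()] object.
#' @return an `nnpi_dataset` satisfying all core invariants.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pool <- config$species_pool_size
  n_nn <- round(pool * config$nonnative_fraction)

  # --- taxon trait table
  taxon_id <- sprintf("T%04d", seq_len(pool))
  nn <- seq_len(pool) <= n_nn
  native_status <- character(pool)
  native_status[nn] <- sample(nonnative_statuses, n_nn, replace = TRUE,
                              prob = c(0.8, 0.1, 0.1))
  native_status[!nn] <- sample(c("NATIVE", "UNDETERMINED"), pool - n_nn,
                               replace = TRUE, prob = c(0.95, 0.05))
  growth_habit <- sample(growth_habits, pool, replace = TRUE,
                         prob = c(0.40, 0.25, 0.10, 0.15, 0.10))
  # nonnatives skew toward drier indicator statuses
  wis <- integer(pool)
  wis[nn] <- sample(1:5, n_nn, replace = TRUE,
                    prob = c(0.08, 0.12, 0.20, 0.30, 0.30))
  wis[!nn] <- sample(1:5, pool - n_nn, replace = TRUE,
                     prob = c(0.30, 0.25, 0.20, 0.15, 0.10))
  wis[stats::runif(pool) < 0.05] <- NA
  traits <- data.frame(taxon_id = taxon_id, native_status = native_status,
                       growth_habit = growth_habit, wis = wis,
                       stringsAsFactors = FALSE)

  # --- site frame
  n <- config$n_sites
  sites <- data.frame(
    site_id = sprintf("S%04d", seq_len(n)), visit_no = 1L,
    x = stats::runif(n), y = stats::runif(n),
    weight = stats::rgamma(n, shape = config$weight_shape,
                           scale = config$weight_scale),
    ecoregion = sample(ecoregions, n, replace = TRUE,
                       prob = c(0.25, 0.25, 0.2, 0.15, 0.15)),
    wetland_type = sample(wetland_types, n, replace = TRUE,
                          prob = c(0.15, 0.1, 0.4, 0.35)),
    is_probability = stats::runif(n) > config$nonprobability_fraction,
    stringsAsFactors = FALSE)
  # relative hydric condition by wetland type (drives the wetland index)
  wetness_base <- c(EH = 1.5, EW = 1.8, PRLH = 2.0, PRLW = 2.6)
  site_wetness <- wetness_base[sites$wetland_type] +
    stats::rnorm(n, 0, 0.35)
  site_wetness <- pmin(pmax(site_wetness, 1), 5)
  sites$bareground <- pmin(stats::rbeta(n, 1.2, 9) * 100 *
                             ifelse(sites$ecoregion %in% c("XER", "IPL"),
                                    2.2, 1), 100)

  # --- latent disturbance and its eight raw sub-indices
  d_latent <- stats::rbeta(n, 1.3, 2.2)
  dist_idx <- sapply(1:8, function(k) {
    stats::rgamma(n, shape = 2, scale = 0.4 + 2.2 * d_latent)
  })
  disturbance <- data.frame(site_id = sites$site_id, dist_idx,
                            stringsAsFactors = FALSE)
  names(disturbance) <- c("site_id", paste0("idx", 1:8))

  # --- per-taxon selection weight at each site
  stratum_mult <- config$ecoregion_mult[sites$ecoregion] *
    config$wetland_type_mult[sites$wetland_type]
  draw_community <- function(i) {
    rich <- max(stats::rpois(1, config$richness_mean), 1)
    rich <- min(rich, pool)
    wis_eff <- ifelse(is.na(wis), 3, wis)
    w_taxon <- exp(-0.8 * abs(wis_eff - site_wetness[i]))
    w_taxon[nn] <- w_taxon[nn] * config$nonnative_weight * stratum_mult[i] *
      exp(config$disturbance_effect * (d_latent[i] - 0.5))
    sample(taxon_id, rich, prob = w_taxon)
  }

  # --- realize the true field state (plot occupancy + covers) once per site
  realize_site <- function(i, community) {
    rows <- lapply(community, function(t) {
      p_occ <- stats::runif(1, 0.3, 1)
      plots <- which(stats::runif(config$n_plots) < p_occ)
      if (length(plots) == 0) plots <- sample.int(config$n_plots, 1)
      data.frame(site_id = sites$site_id[i], visit_no = NA_integer_,
                 plot_id = plots, taxon_id = t,
                 cover = rtrunc_cover(length(plots), config$cover_meanlog,
                                      config$cover_sdlog),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  # --- one field measurement of a site: the true covers perturbed so the
  #     observed nonnative relative cover is truth + N(0, revisit_noise_sd)
  observe_visit <- function(true_cov, visit_no) {
    cov <- true_cov
    cov$visit_no <- visit_no
    is_nn_row <- cov$taxon_id %in% taxon_id[nn]
    if (config$revisit_noise_sd > 0 && any(is_nn_row) && !all(is_nn_row)) {
      r_true <- sum(cov$cover[is_nn_row]) / sum(cov$cover) * 100
      target <- r_true + stats::rnorm(1, 0, config$revisit_noise_sd)
      cov$cover <- apply_metric_noise(cov$cover, is_nn_row, target)
    }
    cov
  }

  communities <- lapply(seq_len(n), draw_community)
  true_covers <- lapply(seq_len(n), function(i) realize_site(i, communities[[i]]))
  cover1 <- lapply(true_covers, observe_visit, visit_no = 1L)

  # --- revisits: same true field state, independent measurement realization
  n_rev <- round(config$revisit_fraction * n)
  rev_sites <- if (n_rev > 0) sort(sample.int(n, n_rev)) else integer(0)
  cover2 <- lapply(true_covers[rev_sites], observe_visit, visit_no = 2L)
  if (n_rev > 0) {
    sites2 <- sites[rev_sites, ]
    sites2$visit_no <- 2L
    sites_all <- rbind(sites, sites2)
  } else {
    sites_all <- sites
  }
  cover <- do.call(rbind, c(cover1, cover2))
  rownames(cover) <- NULL
  rownames(sites_all) <- NULL
  as_dataset(cover, traits, sites_all, disturbance,
             n_plots = config$n_plots)
}
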