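# Design-based population inference -----------------------------------------

# With-replacement (pwr) variance of an estimated total sum(z), z_i = w_i*y_i.
srs_total_var <- function(z) {
  n <- length(z)
  if (n < 2) return(NA_real_)
  n * stats::var(z)
}

#' Local-neighborhood variance of an estimated total
#'
#' Variance estimator for totals from spatially balanced probability samples:
#' each site's weighted contribution is contrasted with the weighted mean of
#' its spatial neighborhood (the `nbh_size` nearest sites by Euclidean
#' distance, the site itself included), and the squared deviations are
#' accumulated with neighborhood weights that are iteratively rescaled so
#' that every site contributes unit weight both as a neighborhood centre and
#' as a member. For spatially unstructured data it tracks the
#' with-replacement estimator; under spatial structure it exploits the
#' spatial balance of the design and is smaller.
#'
#' @param contributions numeric vector, the per-site weighted contributions
#'   `w_i * y_i` (or residual contributions for a ratio mean).
#' @param coords two-column matrix or data.frame of planar site coordinates.
#' @param nbh_size neighborhood size (default 4, the conventional choice).
#' @return a non-negative variance estimate. With fewer sites than
#'   `nbh_size` it falls back to the with-replacement estimator with a
#'   warning.
#' @export
local_mean_variance <- function(contributions, coords, nbh_size = 4L) {
  z <- as.numeric(contributions)
  n <- length(z)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n, ncol(coords) == 2)
  if (n < nbh_size) {
    warning("fewer sites than the neighborhood size; ",
            "falling back to the with-replacement variance estimator")
    return(srs_total_var(z))
  }
  d <- as.matrix(stats::dist(coords))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbh <- order(d[i, ])[seq_len(nbh_size)]  # self included (distance 0)
    w[i, nbh] <- 1 / nbh_size
  }
  # Rescale so rows and columns both sum to 1 (iterative proportional fitting);
  # keeps total weight n while symmetrising each site's dual role.
  for (iter in 1:25) {
    w <- w / rowSums(w)
    cs <- colSums(w)
    cs[cs == 0] <- 1
    w <- sweep(w, 2, cs, "/")
    if (max(abs(rowSums(w) - 1)) < 1e-10) break
  }
  w <- w / rowSums(w)
  zbar <- as.numeric(w %*% z)
  # Per-neighborhood weighted squared deviations, each inflated by
  # 1/(1 - sum(w^2)) so the estimator is unbiased when contributions are
  # spatially unstructured (the weighted-variance analogue of n/(n-1)).
  dev2 <- rowSums(w * (matrix(z, n, n, byrow = TRUE) - zbar)^2)
  denom <- pmax(1 - rowSums(w^2), 0.05)
  sum(dev2 / denom)
}

ci95 <- function(estimate, se, lower_bound = -Inf) {
  lo <- estimate - 1.96 * se
  hi <- estimate + 1.96 * se
  list(lo = pmax(lo, lower_bound), hi = hi)
}

prob_frame <- function(sites) {
  keep <- sites$visit_no == 1 & as.logical(sites$is_probability)
  sites[keep, , drop = FALSE]
}

domain_split <- function(sites, by = c("national", "ecoregion",
                                       "wetland_type")) {
  by <- match.arg(by)
  if (by == "national") {
    list(national = sites)
  } else {
    split(sites, sites[[by]])
  }
}

#' Weighted area extent by stressor-level category
#'
#' Estimates, for each domain and each of the four stressor levels, the
#' wetland area in that category as the Horvitz-Thompson total of the site
#' weights (hectares), with a standard error, a two-sided 95% confidence
#' interval (truncated at zero) and the percent of the domain's total
#' estimated area. Only first-visit probability sites contribute. Category
#' areas within a domain sum exactly to the domain's total weight.
#'
#' @param sites site table (`nnpi_dataset$sites`).
#' @param nnpi classification table from [classify_nnpi()].
#' @param by domain specification: `"national"`, `"ecoregion"` or
#'   `"wetland_type"`.
#' @param variance `"local"` (neighborhood estimator, default) or `"srs"`
#'   (with-replacement).
#' @param nbh_size neighborhood size for the local estimator.
#' @return data.frame with one row per domain x category: `domain`,
#'   `domain_value`, `category`, `n_sites`, `area_ha`, `se`, `lo`, `hi`,
#'   `pct_of_domain`.
#' @export
category_extent <- function(sites, nnpi, by = c("national", "ecoregion",
                                                "wetland_type"),
                            variance = c("local", "srs"), nbh_size = 4L) {
  by <- match.arg(by)
  variance <- match.arg(variance)
  st <- prob_frame(sites)
  if (nrow(st) == 0) {
    return(data.frame(domain = character(), domain_value = character(),
                      category = character(), n_sites = integer(),
                      area_ha = numeric(), se = numeric(), lo = numeric(),
                      hi = numeric(), pct_of_domain = numeric()))
  }
  cls <- nnpi[nnpi$visit_no == 1, ]
  idx <- match(st$site_id, cls$site_id)
  if (anyNA(idx)) {
    stop("sites without a classification row: ",
         paste(utils::head(st$site_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  st$category <- as.character(cls$overall[idx])
  rows <- list()
  for (dom in names(domain_split(st, by))) {
    d <- domain_split(st, by)[[dom]]
    total_w <- sum(d$weight)
    for (cat in stressor_level_names) {
      y <- as.numeric(d$category == cat)
      z <- d$weight * y
      est <- sum(z)
      v <- if (variance == "srs" || nrow(d) < nbh_size) {
        srs_total_var(z)
      } else {
        local_mean_variance(z, d[c("x", "y")], nbh_size)
      }
      se <- sqrt(max(v, 0))
      ci <- ci95(est, se, lower_bound = 0)
      rows[[length(rows) + 1]] <- data.frame(
        domain = by, domain_value = dom, category = cat,
        n_sites = sum(y), area_ha = est, se = se, lo = ci$lo, hi = ci$hi,
        pct_of_domain = est / total_w * 100, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population-weighted mean of a site attribute
#'
#' The ratio estimator `sum(w_i * y_i) / sum(w_i)` over first-visit
#' probability sites in each domain, with a Taylor-linearised standard error
#' (residual contributions `w_i (y_i - mean) / sum(w)` fed to the chosen
#' variance estimator) and a two-sided 95% CI. A single-site domain returns
#' its value with an NA standard error.
#'
#' @param values numeric vector aligned row-for-row with `sites`.
#' @param sites site table.
#' @inheritParams category_extent
#' @param metric label carried into the output.
#' @return data.frame with one row per domain: `domain`, `domain_value`,
#'   `metric`, `n_sites`, `mean`, `se`, `lo`, `hi`.
#' @export
population_mean <- function(values, sites, by = c("national", "ecoregion",
                                                  "wetland_type"),
                            variance = c("local", "srs"), nbh_size = 4L,
                            metric = "value") {
  by <- match.arg(by)
  variance <- match.arg(variance)
  stopifnot(length(values) == nrow(sites))
  sites$.y <- values
  st <- prob_frame(sites)
  st <- st[is.finite(st$.y), , drop = FALSE]
  rows <- list()
  for (dom in names(domain_split(st, by))) {
    d <- domain_split(st, by)[[dom]]
    n <- nrow(d)
    m <- sum(d$weight * d$.y) / sum(d$weight)
    if (n < 2) {
      se <- NA_real_
    } else {
      resid <- d$weight * (d$.y - m) / sum(d$weight)
      v <- if (variance == "srs" || n < nbh_size) {
        srs_total_var(resid)
      } else {
        local_mean_variance(resid, d[c("x", "y")], nbh_size)
      }
      se <- sqrt(max(v, 0))
    }
    ci <- if (is.na(se)) list(lo = NA_real_, hi = NA_real_) else ci95(m, se)
    rows[[length(rows) + 1]] <- data.frame(
      domain = by, domain_value = dom, metric = metric, n_sites = n,
      mean = m, se = se, lo = ci$lo, hi = ci$hi, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Do two 95% confidence intervals overlap?
#'
#' Convenience flag for the conventional "nonoverlapping CIs" comparison of
#' subpopulation estimates (no multiplicity adjustment).
#'
#' @param lo1,hi1,lo2,hi2 interval endpoints.
#' @return logical: TRUE when the intervals do not overlap.
#' @export
ci_nonoverlap <- function(lo1, hi1, lo2, hi2) {
  hi1 < lo2 | hi2 < lo1
}

#' Signal-to-noise repeatability of a metric
#'
#' Signal is the variance of the metric across all sites (first visits);
#' noise is the within-season revisit variance, estimated as the mean over
#' revisit pairs of half the squared visit-1/visit-2 difference. Metrics
#' with a ratio above 2 are conventionally considered able to make
#' ecological distinctions.
#'
#' @param values data.frame with columns `site_id`, `visit_no`, `value`.
#' @param metric label carried into the result.
#' @return list with `metric`, `signal_var`, `noise_var`, `ratio` (Inf when
#'   noise is zero but signal is positive), `n_sites`, `n_pairs`.
#' @export
signal_to_noise <- function(values, metric = "value") {
  check_schema(values, c("site_id", "visit_no", "value"), "values")
  v1 <- values[values$visit_no == 1, ]
  v2 <- values[values$visit_no == 2, ]
  if (nrow(v1) < 2) stop("need at least 2 sites for the signal variance",
                         call. = FALSE)
  idx <- match(v2$site_id, v1$site_id)
  pairs <- !is.na(idx)
  if (sum(pairs) < 2) stop("need at least 2 revisit pairs for the noise variance",
                           call. = FALSE)
  diffs <- v2$value[pairs] - v1$value[idx[pairs]]
  signal <- stats::var(v1$value)
  noise <- mean(diffs^2 / 2)
  if (noise == 0 && signal == 0) {
    stop("metric is constant across sites and visits; S:N undefined",
         call. = FALSE)
  }
  ratio <- if (noise == 0) Inf else signal / noise
  list(metric = metric, signal_var = signal, noise_var = noise,
       ratio = ratio, n_sites = nrow(v1), n_pairs = sum(pairs))
}
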