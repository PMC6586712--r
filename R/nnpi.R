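# Stressor-level decision matrix --------------------------------------------

stressor_level_names <- c("low", "moderate", "high", "very_high")
combined_level_names <- c("LM", "HVH")

#' Ordered stressor-level factor
#'
#' @param x character vector of levels (`"low"`, `"moderate"`, `"high"`,
#'   `"very_high"`) or an integer 1..4.
#' @return an ordered factor low < moderate < high < very_high.
#' @export
stressor_level <- function(x) {
  if (is.numeric(x)) x <- stressor_level_names[x]
  factor(x, levels = stressor_level_names, ordered = TRUE)
}

#' Exceedance threshold matrix for the three component metrics
#'
#' Three ascending cutpoints per metric. A metric value at or below the
#' first cutpoint is low; above the first and at or below the second,
#' moderate; above the second and at or below the third, high; above the
#' third, very high — boundary values belong to the lower category. The
#' defaults are the published decision-matrix values: relative cover
#' (1, 15, 40), richness (5, 10, 15), relative frequency (10, 30, 60).
#'
#' @param rel_cover,richness,rel_freq numeric length-3 ascending cutpoints.
#' @return an object of class `nnpi_thresholds`.
#' @export
nnpi_thresholds <- function(rel_cover = c(1, 15, 40),
                            richness = c(5, 10, 15),
                            rel_freq = c(10, 30, 60)) {
  th <- list(rel_cover = as.numeric(rel_cover),
             richness = as.numeric(richness),
             rel_freq = as.numeric(rel_freq))
  for (m in names(th)) {
    if (length(th[[m]]) != 3 || any(!is.finite(th[[m]])) ||
        any(diff(th[[m]]) <= 0)) {
      stop(sprintf("thresholds for %s must be three strictly ascending values",
                   m), call. = FALSE)
    }
  }
  structure(th, class = "nnpi_thresholds")
}

#' Stressor level of a single metric value
#'
#' @param value non-negative metric value(s).
#' @param metric one of `"rel_cover"`, `"richness"`, `"rel_freq"`.
#' @param thresholds an [nnpi_thresholds()] object.
#' @return ordered stressor-level factor, same length as `value`.
#' @export
level_for_metric <- function(value, metric = c("rel_cover", "richness",
                                               "rel_freq"),
                             thresholds = nnpi_thresholds()) {
  metric <- match.arg(metric)
  stopifnot(inherits(thresholds, "nnpi_thresholds"))
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("metric values must be finite and non-negative", call. = FALSE)
  }
  cut <- thresholds[[metric]]
  idx <- 1L + (value > cut[1]) + (value > cut[2]) + (value > cut[3])
  stressor_level(idx)
}

#' Collapse the four stressor levels to the two combined classes
#'
#' Low and moderate map to `LM`; high and very high map to `HVH`.
#'
#' @param level stressor-level factor or character vector.
#' @return factor with levels `LM`, `HVH`.
#' @export
combine_level <- function(level) {
  lv <- stressor_level(as.character(level))
  if (anyNA(lv) && !anyNA(level)) stop("invalid stressor level", call. = FALSE)
  factor(ifelse(as.integer(lv) >= 3L, "HVH", "LM"),
         levels = combined_level_names)
}

#' Classify sites by the max-filter decision matrix
#'
#' Each of the three component metrics (nonnative relative cover, richness,
#' relative frequency) is bracketed against its exceedance thresholds; the
#' overall indicator is the highest stressor level observed across the three
#' metrics. Exceeding a threshold for any one metric therefore moves the
#' site to the next higher stress level. A site with no vegetation has all
#' metrics 0, classifies as low, and is flagged.
#'
#' @param nn_richness,nn_rel_freq,nn_rel_cover numeric vectors (recycled to
#'   common length) of the per-site metric values.
#' @param thresholds an [nnpi_thresholds()] object.
#' @param site_id optional identifiers carried into the result.
#' @return data.frame with the metric values, per-metric levels
#'   (`level_cover`, `level_richness`, `level_freq`), the `overall` level,
#'   the `combined` two-class rollup, and an `unvegetated` flag.
#' @export
classify_site <- function(nn_richness, nn_rel_freq, nn_rel_cover,
                          thresholds = nnpi_thresholds(), site_id = NULL) {
  n <- max(length(nn_richness), length(nn_rel_freq), length(nn_rel_cover))
  nn_richness <- rep_len(nn_richness, n)
  nn_rel_freq <- rep_len(nn_rel_freq, n)
  nn_rel_cover <- rep_len(nn_rel_cover, n)
  l_cov <- level_for_metric(nn_rel_cover, "rel_cover", thresholds)
  l_ric <- level_for_metric(nn_richness, "richness", thresholds)
  l_frq <- level_for_metric(nn_rel_freq, "rel_freq", thresholds)
  overall <- stressor_level(pmax(as.integer(l_cov), as.integer(l_ric),
                                 as.integer(l_frq)))
  out <- data.frame(
    nn_richness = nn_richness, nn_rel_freq = nn_rel_freq,
    nn_rel_cover = nn_rel_cover,
    level_cover = l_cov, level_richness = l_ric, level_freq = l_frq,
    overall = overall, combined = combine_level(overall),
    unvegetated = nn_richness == 0 & nn_rel_freq == 0 & nn_rel_cover == 0,
    stringsAsFactors = FALSE)
  if (!is.null(site_id)) out <- cbind(site_id = site_id, out)
  out
}

#' Classify every site visit of a metric table
#'
#' @param metrics output of [site_metrics()] (needs `site_id`, `visit_no`,
#'   `nn_richness`, `nn_rel_freq`, `nn_rel_cover`).
#' @param thresholds an [nnpi_thresholds()] object.
#' @return the classification table of [classify_site()] with `site_id` and
#'   `visit_no` prepended.
#' @export
classify_nnpi <- function(metrics, thresholds = nnpi_thresholds()) {
  needed <- c("site_id", "visit_no", "nn_richness", "nn_rel_freq",
              "nn_rel_cover")
  check_schema(metrics, needed, "metrics")
  res <- classify_site(metrics$nn_richness, metrics$nn_rel_freq,
                       metrics$nn_rel_cover, thresholds)
  cbind(metrics[c("site_id", "visit_no")], res)
}
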