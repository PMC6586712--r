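# Class-balanced random forest ----------------------------------------------

#' Random-forest configuration
#'
#' Defaults follow the conventional classification setup: 1000 trees and
#' `mtry = floor(sqrt(p))` candidate predictors per node. Each tree is grown
#' on a balanced bootstrap drawing, with replacement, the same number of
#' cases from both combined stressor classes — the size of the minority
#' class — to counter class imbalance.
#'
#' @param n_trees number of trees.
#' @param mtry candidate predictors per split; NULL means `floor(sqrt(p))`.
#' @param seed integer RNG seed for reproducible fits.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000L, mtry = NULL, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be positive", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)), class = "forest_config")
}

#' Fit a class-balanced random forest for combined stressor status
#'
#' Trains a random forest on the per-site predictor table with the two-class
#' combined stressor level (`LM` vs `HVH`) as response. Every tree's
#' bootstrap sample contains exactly `min(class counts)` cases of each
#' class, drawn with replacement within class (downsampling of the majority
#' class). Out-of-bag (OOB) vote counts are retained for performance and
#' importance estimation. Survey weights are not used.
#'
#' @param predictors data.frame of predictor columns (numeric or factor), no
#'   missing values.
#' @param labels factor (or character) with levels `LM` and `HVH`.
#' @param config a [forest_config()].
#' @return an object of class `nnpi_forest`: list with the underlying
#'   `randomForest` fit (`model`), OOB vote counts (`votes`), `labels`,
#'   `config` and the per-class bootstrap size (`sampsize`).
#' @export
fit_balanced_forest <- function(predictors, labels,
                                config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  predictors <- as.data.frame(predictors)
  labels <- factor(as.character(labels), levels = combined_level_names)
  if (anyNA(labels)) stop("labels must be LM or HVH", call. = FALSE)
  if (anyNA(predictors)) {
    stop("predictor table contains missing values", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("each combined class needs at least 2 sites", call. = FALSE)
  }
  constant <- vapply(predictors, function(x) length(unique(x)) == 1,
                     logical(1))
  if (any(constant)) {
    message("constant predictor(s) retained: ",
            paste(names(predictors)[constant], collapse = ", "))
  }
  p <- ncol(predictors)
  mtry <- if (is.null(config$mtry)) max(floor(sqrt(p)), 1) else config$mtry
  m <- min(counts)
  set.seed(config$seed)
  model <- randomForest::randomForest(
    x = predictors, y = labels, ntree = config$n_trees, mtry = mtry,
    strata = labels, sampsize = c(m, m), replace = TRUE,
    importance = TRUE, keep.inbag = TRUE, keep.forest = TRUE,
    norm.votes = FALSE)
  structure(list(model = model, votes = model$votes, labels = labels,
                 config = config, sampsize = m, predictors = predictors),
            class = "nnpi_forest")
}

#' @export
print.nnpi_forest <- function(x, ...) {
  perf <- oob_performance(x$votes, x$labels)
  cat("<nnpi_forest>\n")
  cat(sprintf("  %d trees, mtry %d, balanced bootstrap %d + %d per tree\n",
              x$config$n_trees, x$model$mtry, x$sampsize, x$sampsize))
  cat(sprintf("  OOB correct: all %.1f%% | LM %.1f%% | HVH %.1f%%\n",
              perf$pcc_all, perf$pcc_lm, perf$pcc_hvh))
  invisible(x)
}

#' Out-of-bag percent correctly classified
#'
#' Each site is predicted by majority vote of the trees for which it was out
#' of bag (ties go to `HVH`, the stress-conservative call). Returns the
#' percent of sites correctly classified overall and within each class.
#' Sites with no OOB votes are excluded with a warning.
#'
#' @param votes matrix of OOB vote counts with columns `LM` and `HVH` (as in
#'   `nnpi_forest$votes`).
#' @param labels true combined classes.
#' @return list with `pcc_all`, `pcc_lm`, `pcc_hvh` (percent) and the
#'   majority-vote `predicted` factor.
#' @export
oob_performance <- function(votes, labels) {
  votes <- as.matrix(votes)
  if (nrow(votes) == 0) stop("empty vote set", call. = FALSE)
  stopifnot(all(c("LM", "HVH") %in% colnames(votes)),
            nrow(votes) == length(labels))
  labels <- factor(as.character(labels), levels = combined_level_names)
  seen <- rowSums(votes) > 0
  if (!all(seen)) {
    warning(sprintf("%d site(s) never out of bag; excluded", sum(!seen)))
    votes <- votes[seen, , drop = FALSE]
    labels <- labels[seen]
  }
  predicted <- factor(ifelse(votes[, "HVH"] >= votes[, "LM"], "HVH", "LM"),
                      levels = combined_level_names)
  correct <- predicted == labels
  list(pcc_all = mean(correct) * 100,
       pcc_lm = mean(correct[labels == "LM"]) * 100,
       pcc_hvh = mean(correct[labels == "HVH"]) * 100,
       predicted = predicted)
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For each predictor, the mean over trees of the drop in OOB accuracy when
#' that predictor's OOB values are permuted within the tree — higher values
#' mean greater importance. A predictor the forest never uses (e.g. a
#' constant) scores exactly 0.
#'
#' @param fit an `nnpi_forest`.
#' @return named numeric vector (one entry per predictor), descending.
#' @export
permutation_importance <- function(fit) {
  stopifnot(inherits(fit, "nnpi_forest"))
  imp <- randomForest::importance(fit$model, type = 1, scale = FALSE)[, 1]
  sort(imp, decreasing = TRUE)
}

#' Partial dependence of the HVH probability on one predictor
#'
#' For each grid value v, the predictor is pinned to v for every site and
#' the forest's predicted probability of the high-very-high class is
#' averaged over sites — the marginal effect of the predictor with the
#' others averaged out.
#'
#' @param fit an `nnpi_forest`.
#' @param predictor column name.
#' @param grid numeric grid (or factor levels for a categorical predictor);
#'   default 25 equally spaced points between the 1st and 99th percentile.
#' @return data.frame with columns `value` and `prob_hvh`.
#' @export
partial_dependence <- function(fit, predictor, grid = NULL) {
  stopifnot(inherits(fit, "nnpi_forest"))
  data <- fit$predictors
  if (!predictor %in% names(data)) {
    stop(sprintf("unknown predictor: %s", predictor), call. = FALSE)
  }
  x <- data[[predictor]]
  if (is.null(grid)) {
    if (is.factor(x) || is.character(x)) {
      grid <- if (is.factor(x)) levels(x) else unique(x)
    } else {
      q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
      grid <- seq(q[1], q[2], length.out = 25)
    }
  }
  if (length(grid) == 0) stop("empty grid", call. = FALSE)
  prob <- vapply(grid, function(v) {
    d <- data
    d[[predictor]] <- if (is.factor(x)) {
      factor(rep(v, nrow(d)), levels = levels(x))
    } else {
      rep(v, nrow(d))
    }
    mean(stats::predict(fit$model, d, type = "prob")[, "HVH"])
  }, numeric(1))
  data.frame(value = grid, prob_hvh = prob)
}

#' Assemble the per-site predictor table for the forest
#'
#' Joins, for first visits of all sampled sites (probability and not), the
#' vegetation/environment metrics (wetland index, native richness, the five
#' native growth-habit covers, bareground), the overall disturbance index,
#' and the ecoregion and wetland-type factors, against the combined
#' stressor-level response. Sites with any missing predictor (e.g. an
#' undefined wetland index) are dropped with a message.
#'
#' @param metrics [site_metrics()] table.
#' @param nnpi [classify_nnpi()] table.
#' @param disturbance_scored [score_disturbance()] table.
#' @param sites site table.
#' @param extra optional data.frame of additional per-site predictor columns
#'   plus a `site_id` column.
#' @return list with `predictors` (data.frame) and `labels` (factor LM/HVH).
#' @export
build_rf_predictors <- function(metrics, nnpi, disturbance_scored, sites,
                                extra = NULL) {
  m1 <- metrics[metrics$visit_no == 1, ]
  c1 <- nnpi[nnpi$visit_no == 1, ]
  s1 <- sites[sites$visit_no == 1, ]
  df <- data.frame(
    site_id = m1$site_id,
    wetland_index = m1$wetland_index,
    native_richness = m1$native_richness,
    native_cover_forb = m1$native_cover_forb,
    native_cover_graminoid = m1$native_cover_graminoid,
    native_cover_vine = m1$native_cover_vine,
    native_cover_shrub = m1$native_cover_shrub,
    native_cover_tree = m1$native_cover_tree,
    bareground = m1$bareground,
    stringsAsFactors = FALSE)
  df$disturbance <- disturbance_scored$overall[
    match(df$site_id, disturbance_scored$site_id)]
  df$ecoregion <- factor(s1$ecoregion[match(df$site_id, s1$site_id)],
                         levels = ecoregions)
  df$wetland_type <- factor(s1$wetland_type[match(df$site_id, s1$site_id)],
                            levels = wetland_types)
  if (!is.null(extra)) {
    idx <- match(df$site_id, extra$site_id)
    for (col in setdiff(names(extra), "site_id")) df[[col]] <- extra[[col]][idx]
  }
  labels <- c1$combined[match(df$site_id, c1$site_id)]
  complete <- stats::complete.cases(df) & !is.na(labels)
  if (!all(complete)) {
    message(sprintf("dropping %d site(s) with missing predictors or labels",
                    sum(!complete)))
  }
  list(predictors = df[complete, setdiff(names(df), "site_id")],
       labels = factor(as.character(labels[complete]),
                       levels = combined_level_names),
       site_id = df$site_id[complete])
}
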