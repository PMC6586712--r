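sep_data <- function(n = 300, seed = 1) {
  set.seed(seed)
  x <- data.frame(signal = runif(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- factor(ifelse(x$signal > 0.6, "HVH", "LM"), levels = c("LM", "HVH"))
  list(x = x, y = y)
}

test_that("every tree trains on an equal-count two-class bootstrap", {
  d <- sep_data(200, 3)
  fit <- fit_balanced_forest(d$x, d$y, forest_config(n_trees = 50, seed = 4))
  m <- fit$sampsize
  expect_equal(m, min(table(d$y)))
  inb <- fit$model$inbag
  expect_equal(unique(colSums(inb[d$y == "LM", , drop = FALSE])), m)
  expect_equal(unique(colSums(inb[d$y == "HVH", , drop = FALSE])), m)
})

test_that("the fit is reproducible under a fixed seed", {
  d <- sep_data(150, 5)
  cfg <- forest_config(n_trees = 60, seed = 11)
  f1 <- fit_balanced_forest(d$x, d$y, cfg)
  f2 <- fit_balanced_forest(d$x, d$y, cfg)
  expect_identical(f1$votes, f2$votes)
  expect_identical(permutation_importance(f1), permutation_importance(f2))
})

test_that("fitting rejects degenerate inputs and flags constants", {
  d <- sep_data(50, 6)
  bad <- d$y; bad[] <- "LM"
  expect_error(fit_balanced_forest(d$x, bad, forest_config(10)), "at least 2")
  xm <- d$x; xm$signal[1] <- NA
  expect_error(fit_balanced_forest(xm, d$y, forest_config(10)), "missing")
  xc <- d$x; xc$flat <- 1
  expect_message(fit_balanced_forest(xc, d$y, forest_config(10, seed = 2)),
                 "constant")
})

test_that("OOB majority-vote performance counts correctly, ties to HVH", {
  votes <- matrix(c(9, 1,   8, 2,   3, 7,   6, 4), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("LM", "HVH")))
  labels <- c("LM", "LM", "HVH", "HVH")
  perf <- oob_performance(votes, labels)
  expect_equal(perf$pcc_all, 75)
  expect_equal(perf$pcc_lm, 100)
  expect_equal(perf$pcc_hvh, 50)
  # a tie is called HVH (stress-conservative)
  tied <- matrix(c(5, 5), ncol = 2, dimnames = list(NULL, c("LM", "HVH")))
  expect_equal(as.character(oob_performance(tied, "HVH")$predicted), "HVH")
  expect_error(oob_performance(votes[0, , drop = FALSE], character(0)),
               "empty")
  # a never-OOB site is excluded with a warning
  v2 <- rbind(votes, c(0, 0))
  expect_warning(p2 <- oob_performance(v2, c(labels, "LM")), "never out of bag")
  expect_equal(p2$pcc_all, 75)
})

test_that("permutation importance isolates the informative predictor", {
  d <- sep_data(300, 7)
  fit <- fit_balanced_forest(d$x, d$y, forest_config(n_trees = 200, seed = 8))
  imp <- permutation_importance(fit)
  expect_equal(names(imp)[1], "signal")
  expect_lt(max(abs(imp[c("noise1", "noise2")])), 0.05)
  # a constant predictor scores exactly zero
  xc <- d$x; xc$flat <- 1
  suppressMessages(
    fitc <- fit_balanced_forest(xc, d$y, forest_config(n_trees = 100,
                                                       seed = 9)))
  expect_equal(unname(permutation_importance(fitc)["flat"]), 0)
})

test_that("partial dependence is flat for an ignored predictor, rises with risk", {
  d <- sep_data(300, 10)
  fit <- fit_balanced_forest(d$x, d$y, forest_config(n_trees = 150, seed = 12))
  pd_noise <- partial_dependence(fit, "noise1")
  expect_lt(diff(range(pd_noise$prob_hvh)), 0.1)
  pd_sig <- partial_dependence(fit, "signal")
  expect_equal(nrow(pd_sig), 25)
  # monotone generative risk -> essentially non-decreasing fitted curve
  expect_gt(cor(pd_sig$value, pd_sig$prob_hvh), 0.8)
  expect_gt(mean(pd_sig$prob_hvh[pd_sig$value > 0.7]),
            mean(pd_sig$prob_hvh[pd_sig$value < 0.5]))
  one <- partial_dependence(fit, "signal", grid = 0.5)
  expect_equal(nrow(one), 1)
  expect_error(partial_dependence(fit, "signal", grid = numeric(0)), "empty")
  expect_error(partial_dependence(fit, "ghost"), "unknown predictor")
})

test_that("downsampling improves minority recall on 72/28 imbalanced data", {
  # probabilistic labels so the classes overlap and balance matters
  gains <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 400
    x <- data.frame(u = runif(n), v = rnorm(n))
    p_hvh <- plogis(4 * (x$u - 0.78))   # ~28% HVH, overlapping classes
    y <- factor(ifelse(runif(n) < p_hvh, "HVH", "LM"),
                levels = c("LM", "HVH"))
    bal <- fit_balanced_forest(x, y, forest_config(n_trees = 150, seed = s))
    naive <- randomForest::randomForest(x = x, y = y, ntree = 150,
                                        norm.votes = FALSE)
    rec <- function(votes) {
      pred <- ifelse(votes[, "HVH"] >= votes[, "LM"], "HVH", "LM")
      mean(pred[y == "HVH"] == "HVH")
    }
    rec(bal$votes) - rec(naive$votes)
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("the predictor builder assembles the site-level roster", {
  ds <- generate_dataset(sim_config(n_sites = 60, seed = 14))
  m <- site_metrics(ds)
  cls <- classify_nnpi(m)
  sc <- score_disturbance(ds$disturbance)
  rf_in <- build_rf_predictors(m, cls, sc, ds$sites)
  expect_setequal(names(rf_in$predictors),
                  c("wetland_index", "native_richness", "native_cover_forb",
                    "native_cover_graminoid", "native_cover_vine",
                    "native_cover_shrub", "native_cover_tree", "bareground",
                    "disturbance", "ecoregion", "wetland_type"))
  expect_equal(length(rf_in$labels), nrow(rf_in$predictors))
  expect_false(anyNA(rf_in$predictors))
  expect_s3_class(rf_in$predictors$ecoregion, "factor")
  # extra columns join by site_id
  extra <- data.frame(site_id = ds$sites$site_id[ds$sites$visit_no == 1],
                      precip = runif(60))
  rf_in2 <- build_rf_predictors(m, cls, sc, ds$sites, extra = extra)
  expect_true("precip" %in% names(rf_in2$predictors))
})
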