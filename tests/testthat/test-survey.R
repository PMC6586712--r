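toy_frame <- function(weights, categories, coords = NULL) {
  n <- length(weights)
  sites <- data.frame(
    site_id = sprintf("P%02d", seq_len(n)), visit_no = 1L,
    x = if (is.null(coords)) runif(n) else coords[, 1],
    y = if (is.null(coords)) runif(n) else coords[, 2],
    weight = weights, ecoregion = "CPL", wetland_type = "PRLH",
    is_probability = TRUE, bareground = 0)
  nnpi <- data.frame(site_id = sites$site_id, visit_no = 1L,
                     overall = categories)
  list(sites = sites, nnpi = nnpi)
}

test_that("category areas are the weight sums of member sites", {
  set.seed(1)
  tf <- toy_frame(c(1, 2, 3, 4), c("low", "low", "high", "high"))
  ext <- category_extent(tf$sites, tf$nnpi, variance = "srs")
  expect_equal(ext$area_ha[ext$category == "low"], 3)
  expect_equal(ext$area_ha[ext$category == "high"], 7)
  expect_equal(ext$pct_of_domain[ext$category == "low"], 30)
  expect_equal(ext$pct_of_domain[ext$category == "high"], 70)
  expect_equal(ext$area_ha[ext$category == "moderate"], 0)
  # single-category population
  tf2 <- toy_frame(c(4, 6), c("low", "low"))
  ext2 <- category_extent(tf2$sites, tf2$nnpi, variance = "srs")
  expect_equal(ext2$area_ha[ext2$category == "low"], 10)
  expect_equal(sum(ext2$area_ha), 10)
})

test_that("the with-replacement SE matches the hand-evaluated formula", {
  set.seed(2)
  tf <- toy_frame(c(1, 2, 3, 4), c("low", "low", "high", "high"))
  ext <- category_extent(tf$sites, tf$nnpi, variance = "srs")
  # z for 'low' = (1, 2, 0, 0); V = n/(n-1) * sum((z - mean(z))^2) = 11/3
  expect_equal(ext$se[ext$category == "low"], sqrt(11 / 3))
  # CI is estimate +/- 1.96 SE truncated at zero
  expect_equal(ext$hi[ext$category == "low"], 3 + 1.96 * sqrt(11 / 3))
  expect_equal(ext$lo[ext$category == "low"], 0)
})

test_that("category areas conserve the domain's total weight", {
  ds <- generate_dataset(sim_config(n_sites = 150, seed = 13))
  cls <- classify_nnpi(site_metrics(ds))
  for (by in c("national", "ecoregion", "wetland_type")) {
    ext <- category_extent(ds$sites, cls, by = by, variance = "srs")
    for (dom in unique(ext$domain_value)) {
      in_dom <- ds$sites$visit_no == 1 & ds$sites$is_probability
      if (by != "national") in_dom <- in_dom & ds$sites[[by]] == dom
      expect_equal(sum(ext$area_ha[ext$domain_value == dom]),
                   sum(ds$sites$weight[in_dom]), tolerance = 1e-9)
      expect_equal(sum(ext$pct_of_domain[ext$domain_value == dom]), 100,
                   tolerance = 1e-9)
    }
  }
})

test_that("weight rescaling scales areas and SEs, leaves shares and means", {
  ds <- generate_dataset(sim_config(n_sites = 80, seed = 17))
  cls <- classify_nnpi(site_metrics(ds))
  ext1 <- category_extent(ds$sites, cls, variance = "local")
  scaled <- ds$sites
  scaled$weight <- scaled$weight * 3
  ext3 <- category_extent(scaled, cls, variance = "local")
  expect_equal(ext3$area_ha, 3 * ext1$area_ha, tolerance = 1e-9)
  expect_equal(ext3$se, 3 * ext1$se, tolerance = 1e-9)
  expect_equal(ext3$pct_of_domain, ext1$pct_of_domain, tolerance = 1e-9)
  m <- site_metrics(ds)
  v <- m$nn_rel_cover[match(paste(ds$sites$site_id, ds$sites$visit_no),
                            paste(m$site_id, m$visit_no))]
  pm1 <- population_mean(v, ds$sites, variance = "srs")
  pm3 <- population_mean(v, scaled, variance = "srs")
  expect_equal(pm3$mean, pm1$mean, tolerance = 1e-12)
  expect_equal(pm3$se, pm1$se, tolerance = 1e-9)
})

test_that("population means follow the weighted ratio estimator", {
  set.seed(3)
  tf <- toy_frame(c(1, 3), c("low", "low"))
  pm <- population_mean(c(1, 3), tf$sites, variance = "srs")
  expect_equal(pm$mean, 2.5)   # (1*1 + 3*3) / 4
  # equal weights reduce to the arithmetic mean
  tf2 <- toy_frame(c(2, 2, 2), rep("low", 3))
  pm2 <- population_mean(c(1, 5, 9), tf2$sites, variance = "srs")
  expect_equal(pm2$mean, 5)
  expect_true(pm2$mean >= 1 && pm2$mean <= 9)
  # a single-site domain keeps the value and flags SE undefined
  tf3 <- toy_frame(7, "low")
  pm3 <- population_mean(42, tf3$sites, variance = "srs")
  expect_equal(pm3$mean, 42)
  expect_true(is.na(pm3$se))
})

test_that("local-neighborhood variance is zero for constant contributions", {
  set.seed(4)
  xy <- cbind(runif(30), runif(30))
  expect_equal(local_mean_variance(rep(5, 30), xy), 0)
  expect_warning(v <- local_mean_variance(c(1, 2), xy[1:2, ]),
                 "fewer sites")
  expect_equal(v, 2 * var(c(1, 2)))
})

test_that("the local estimator tracks SRS on random data, undercuts it on trends", {
  set.seed(5)
  ratios_rand <- replicate(50, {
    n <- 80; xy <- cbind(runif(n), runif(n)); z <- runif(n, 0, 10)
    local_mean_variance(z, xy) / (n * var(z))
  })
  expect_lt(abs(mean(ratios_rand) - 1), 0.25)
  ratios_trend <- replicate(20, {
    n <- 80; xy <- cbind(runif(n), runif(n))
    z <- 10 * xy[, 1] + rnorm(n, 0, 0.2)
    local_mean_variance(z, xy) / (n * var(z))
  })
  expect_true(all(ratios_trend < 1))
})

test_that("signal-to-noise handles the degenerate repeatability cases", {
  # identical revisit values, varying sites -> infinite ratio
  df <- rbind(data.frame(site_id = 1:10, visit_no = 1, value = 1:10),
              data.frame(site_id = 1:5, visit_no = 2, value = 1:5))
  sn <- signal_to_noise(df)
  expect_equal(sn$noise_var, 0)
  expect_true(is.infinite(sn$ratio))
  # everything constant -> undefined
  dfc <- df; dfc$value <- 3
  expect_error(signal_to_noise(dfc), "undefined")
  # too few pairs
  expect_error(signal_to_noise(df[c(1:10, 11), ]), "revisit pairs")
})

test_that("nonoverlap flags only disjoint confidence intervals", {
  expect_true(ci_nonoverlap(0, 1, 2, 3))
  expect_false(ci_nonoverlap(0, 2, 1, 3))
  expect_false(ci_nonoverlap(0, 2, 2, 3))
})
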