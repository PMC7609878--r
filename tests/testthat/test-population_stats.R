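test_that("gp_histogram normalizes, clips and locates mass", {
  h1 <- gp_histogram(rep(0.21, 50))
  expect_equal(sum(h1$frequencies), 1, tolerance = 1e-9)
  expect_equal(sum(h1$frequencies > 0), 1L)
  set.seed(8)
  for (vals in list(runif(1000, -1, 1), rnorm(500, 0.3, 0.2))) {
    h <- gp_histogram(vals)
    expect_equal(sum(h$frequencies), 1, tolerance = 1e-9)
    expect_true(all(diff(h$bin_centers) > 0))
  }
  # out-of-range values land in edge bins and are counted
  h2 <- gp_histogram(c(-3, 0, 3))
  expect_equal(h2$n_clipped, 2L)
  expect_equal(h2$frequencies[1], 1 / 3)
  expect_equal(h2$frequencies[length(h2$frequencies)], 1 / 3)
  expect_error(gp_histogram(numeric()), "empty-data")
  # Monte-Carlo moment check at n = 1e5
  set.seed(9)
  h3 <- gp_histogram(rnorm(1e5, 0.2, 0.05))
  expect_lt(abs(histogram_mean(h3) - 0.2), 0.005)
})

test_that("single-Gaussian fits recover moments", {
  set.seed(10)
  n <- 20000
  x <- rnorm(n, 0.1, 0.04)
  for (method in c("histogram_ls", "em")) {
    f <- fit_gaussian_mixture(x, k = 1, method = method, seed = 2)
    expect_true(f$converged)
    # within 3 standard errors (sd/sqrt(n)), plus binning slack for the
    # histogram route
    slack <- if (method == "histogram_ls") 0.002 else 0
    expect_lt(abs(f$components$mean - 0.1),
              3 * 0.04 / sqrt(n) + slack)
    expect_lt(abs(f$components$sd - 0.04), 0.002 + slack)
  }
})

test_that("double-Gaussian fits recover well-separated populations", {
  set.seed(11)
  n <- 1e5
  x <- c(rnorm(0.6 * n, -0.1, 0.03), rnorm(0.4 * n, 0.25, 0.05))
  for (method in c("histogram_ls", "em")) {
    f <- fit_gaussian_mixture(x, k = 2, method = method, seed = 4)
    expect_true(f$converged)
    expect_lt(abs(f$components$mean[1] - (-0.1)), 0.01)
    expect_lt(abs(f$components$mean[2] - 0.25), 0.01)
    expect_lt(abs(f$components$weight[1] - 0.6), 0.02)
    expect_true(all(diff(f$components$mean) > 0))  # sorted ascending
    expect_equal(sum(f$components$weight), 1, tolerance = 1e-6)
  }
})

test_that("a symmetric two-component sample splits 50/50", {
  set.seed(12)
  half <- rnorm(20000, 0.2, 0.03)
  x <- c(-half, half)   # exactly symmetric about 0
  f <- fit_gaussian_mixture(x, k = 2, seed = 3)
  expect_lt(abs(f$components$weight[1] - 0.5), 0.02)
  expect_lt(abs(f$components$mean[1] + f$components$mean[2]), 0.01)
})

test_that("component-count selection distinguishes 1 from 2", {
  set.seed(13)
  uni <- rnorm(5000, 0.1, 0.05)
  expect_equal(select_component_count(uni, 1:3, seed = 2)$k, 1L)
  bi <- c(rnorm(3000, -0.11, 0.013), rnorm(1500, 0.18, 0.016))
  expect_equal(select_component_count(bi, 1:3, seed = 2)$k, 2L)
  expect_equal(select_component_count(bi, 2, seed = 2)$k, 2L)
})

test_that("region statistics respect masks and partitions", {
  ph <- small_phantom("none")
  map <- compute_gp_map(ph$image, mode = "band_mean")
  b <- default_basis()
  hom <- compute_gp_map(small_phantom("none", membrane = 0.5,
                                      interior = 0.5)$image,
                        mode = "band_mean")
  expect_equal(region_gp_stats(hom, hom$valid_mask)$sd, 0)
  mem <- region_gp_stats(map, ph$labels == 2L)
  expect_equal(mem$mean, gp_from_spectrum(mix_spectrum(b, 0.8, 500))$gp,
               tolerance = 1e-6)
  # disjoint masks partition the cell pixel count
  n_whole <- region_gp_stats(map, ph$labels > 0L)$n
  expect_equal(region_gp_stats(map, ph$labels == 1L)$n +
               region_gp_stats(map, ph$labels == 2L)$n, n_whole)
})

test_that("well_gp averages flashes and warns when few", {
  b <- default_basis()
  grid <- channel_grid(405, 600, 1)
  pb <- make_basis_spectra(grid, 440, 490, 45)
  one <- mix_spectrum(pb, 0.6, 300)
  same <- replicate(25, one, simplify = FALSE)
  expect_equal(well_gp(same)$gp, gp_from_spectrum(one)$gp)
  expect_warning(w3 <- well_gp(same[1:3]), "flashes")
  expect_equal(w3$gp, gp_from_spectrum(one)$gp)
  # pooling: a two-population well sits strictly between the parts
  hi <- mix_spectrum(pb, 0.9, 300); lo <- mix_spectrum(pb, 0.1, 300)
  pooled <- emission_spectrum(grid, 0.5 * hi$intensity +
                                0.5 * lo$intensity)
  wgp <- well_gp(replicate(25, pooled, simplify = FALSE))$gp
  expect_gt(wgp, gp_from_spectrum(lo)$gp)
  expect_lt(wgp, gp_from_spectrum(hi)$gp)
})

test_that("poisson-noised wells match noiseless GP within 0.01", {
  lv <- c(0.06, 0.75, 2.5)
  noisy <- make_calcium_series(
    calcium_series_config(calcium_levels = lv, seed = 21L), default_basis())
  clean <- make_calcium_series(
    calcium_series_config(calcium_levels = lv, noise_model = "none",
                          seed = 21L), default_basis())
  tn <- plate_gp_table(noisy$records)
  tc <- plate_gp_table(clean$records)
  expect_equal(tn$well, tc$well)
  expect_true(all(abs(tn$gp - tc$gp) < 0.01))
})

test_that("compare_conditions: power, degenerate F and exclusions", {
  set.seed(14)
  gp <- c(rnorm(6, 0.10, 0.03), rnorm(6, 0.30, 0.03))
  cond <- rep(c(0.06, 1.5), each = 6)
  cmp <- compare_conditions(gp, cond)
  expect_lt(cmp$anova$p, 0.05)
  expect_equal(nrow(cmp$tukey), 1L)
  expect_lt(cmp$tukey$p_adj, 0.05)
  # identical values across conditions: F = 0 by convention
  cmp0 <- compare_conditions(rep(0.2, 9), rep(1:3, each = 3))
  expect_equal(cmp0$anova$F, 0)
  expect_warning(
    cmp1 <- compare_conditions(c(0.1, 0.12, 0.3, 0.31, 0.5),
                               c(1, 1, 2, 2, 3)),
    "excluding")
  expect_equal(nrow(cmp1$summaries), 2L)
  # box-plot summaries are recomputable
  set.seed(15)
  v <- rnorm(20, 0.2, 0.1)
  cmpv <- compare_conditions(c(v, v + 1), rep(1:2, each = 20))
  s <- cmpv$summaries[1, ]
  bs <- grDevices::boxplot.stats(v)
  expect_equal(unlist(s[c("q1", "median", "q3")]),
               bs$stats[2:4], ignore_attr = TRUE)
})

test_that("whole-image mixture matches per-compartment means", {
  ph <- small_phantom("poisson", seed = 17L, size = 48L)
  map <- compute_gp_map(ph$image, mode = "band_mean")
  f <- fit_gaussian_mixture(gp_values(map), k = 2, seed = 5)
  mem <- region_gp_stats(map, ph$labels == 2L)$mean
  int <- region_gp_stats(map, ph$labels == 1L)$mean
  expect_lt(abs(f$components$mean[1] - int), 0.05)
  expect_lt(abs(f$components$mean[2] - mem), 0.05)
})

test_that("recovered high-GP mean increases with membrane order", {
  highs <- vapply(c(0.5, 0.7, 0.9), function(mo) {
    ph <- small_phantom("poisson", seed = 23L, membrane = mo,
                        interior = 0.2)
    map <- compute_gp_map(ph$image, mode = "band_mean")
    fit_gaussian_mixture(gp_values(map), k = 2,
                         seed = 5)$components$mean[2]
  }, numeric(1))
  expect_true(all(diff(highs) > 0))
})

test_that("ensemble and imaging routes concord on one phantom", {
  # same two-population composition measured by both paths: differently
  # weighted averages, documented tolerance 0.05 GP
  b <- default_basis()
  ph <- small_phantom("poisson", seed = 19L, size = 48L)
  map <- compute_gp_map(ph$image, mode = "band_mean")
  img_mean <- mean(gp_values(map))
  n_mem <- sum(ph$labels == 2L); n_int <- sum(ph$labels == 1L)
  grid <- channel_grid(405, 600, 1)
  pb <- make_basis_spectra(grid, 440, 490, 45)
  ens <- emission_spectrum(grid,
    n_mem / (n_mem + n_int) * mix_spectrum(pb, 0.8, 500)$intensity +
    n_int / (n_mem + n_int) * mix_spectrum(pb, 0.3, 500)$intensity)
  well <- well_gp(replicate(25, ens, simplify = FALSE))$gp
  expect_lt(abs(well - img_mean), 0.05)
})
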