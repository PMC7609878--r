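test_that("basis spectra are unimodal, nonnegative and GP-separated", {
  b <- default_basis()
  for (s in list(b$ordered_spectrum, b$disordered_spectrum)) {
    expect_true(all(s$intensity >= 0))
    # exactly one local maximum on the grid
    d <- diff(s$intensity)
    expect_equal(sum(diff(sign(d)) < 0), 1L)
  }
  # derived by direct band summation of the two Gaussians on the default
  # grid: the ordered basis is blue-weighted, the disordered red-weighted
  expect_gt(b$gp_ordered, 0)
  expect_lt(b$gp_disordered, 0)
  expect_gt(b$gp_ordered, b$gp_disordered)
})

test_that("degenerate and limit bases behave", {
  grid <- channel_grid(415, 691, 8.9)
  same <- make_basis_spectra(grid, 465, 465, 45)
  expect_equal(same$ordered_spectrum$intensity,
               same$disordered_spectrum$intensity)
  expect_equal(same$gp_ordered - same$gp_disordered, 0)
  flat <- make_basis_spectra(grid, 440, 490, 1e5)
  expect_lt(abs(flat$gp_ordered - flat$gp_disordered), 1e-6)
  expect_error(make_basis_spectra(grid, 300, 490), "outside grid range")
  expect_error(make_basis_spectra(grid, 440, 490, width = 0), "width")
  expect_error(make_basis_spectra(c(440, 430, 450)), "increasing")
})

test_that("mix_spectrum endpoints, bounds and GP monotonicity", {
  b <- default_basis()
  expect_equal(mix_spectrum(b, 1, 100)$intensity,
               100 * b$ordered_spectrum$intensity)
  expect_equal(mix_spectrum(b, 0, 100)$intensity,
               100 * b$disordered_spectrum$intensity)
  expect_error(mix_spectrum(b, 1.2, 1), "order")
  expect_error(mix_spectrum(b, -0.1, 1), "order")
  # order-to-GP monotonicity whenever the basis separation is positive,
  # checked against direct band summation
  gps <- vapply(seq(0, 1, 0.1), function(phi) {
    sp <- mix_spectrum(b, phi, 100)
    i440 <- brute_band_mean(sp$wavelength, sp$intensity, 440, 10)
    i490 <- brute_band_mean(sp$wavelength, sp$intensity, 490, 10)
    (i440 - i490) / (i440 + i490)
  }, numeric(1))
  expect_true(all(diff(gps) > 0))
  expect_equal(gp_from_spectrum(mix_spectrum(b, 0.7, 50))$gp,
               gps[8], tolerance = 1e-12)
})

test_that("noiseless phantom pixels equal the analytic mixtures", {
  ph <- small_phantom("none")
  b <- default_basis()
  expect_setequal(unique(as.vector(ph$labels)), 0:2)
  mem <- which(ph$labels == 2L, arr.ind = TRUE)[1, ]
  int <- which(ph$labels == 1L & ph$labels != 2L, arr.ind = TRUE)[1, ]
  expect_equal(ph$image$intensities[mem[1], mem[2], ],
               mix_spectrum(b, 0.8, 500)$intensity)
  expect_equal(ph$image$intensities[int[1], int[2], ],
               mix_spectrum(b, 0.3, 500)$intensity)
  bg <- which(ph$labels == 0L, arr.ind = TRUE)[1, ]
  expect_equal(unique(ph$image$intensities[bg[1], bg[2], ]), 2)
})

test_that("phantom generation is a pure function of (config, seed)", {
  a <- small_phantom("poisson", seed = 9L)
  b2 <- small_phantom("poisson", seed = 9L)
  expect_identical(a$image$intensities, b2$image$intensities)
  c2 <- small_phantom("poisson", seed = 10L)
  expect_false(identical(a$image$intensities, c2$image$intensities))
  expect_true(all(a$image$intensities >= 0))
})

test_that("poisson channel means converge to the noiseless spectrum", {
  # Monte-Carlo check of the noise model: a large homogeneous phantom
  # provides ~1e4 replicate interior pixels at brightness 500
  cfg <- cell_phantom_config(image_size = c(128, 128), outer_radius = 60,
                             ring_thickness = 2, interior_order = 0.5,
                             membrane_order = 0.5, brightness = 500,
                             noise_model = "poisson", seed = 4L)
  ph <- make_cell_image(cfg, default_basis())
  interior <- ph$labels == 1L
  expect_gt(sum(interior), 1e4)
  noiseless <- mix_spectrum(default_basis(), 0.5, 500)$intensity
  n <- sum(interior)
  for (k in seq(1, 32, by = 6)) {
    plane <- ph$image$intensities[, , k]
    # Monte-Carlo standard error of a Poisson mean is sqrt(lambda/n)
    expect_lt(abs(mean(plane[interior]) - noiseless[k]),
              max(4 * sqrt(noiseless[k] / n), 0.02 * noiseless[k]))
  }
})

test_that("calcium order map is monotone and series is reproducible", {
  lv <- c(0.06, 0.3, 1.5)
  expect_true(all(diff(calcium_order_map(lv)) > 0))
  cfg <- calcium_series_config(calcium_levels = lv, seed = 5L,
                               wells_per_level = 2L)
  s1 <- make_calcium_series(cfg, default_basis())
  s2 <- make_calcium_series(cfg, default_basis())
  expect_identical(s1$records, s2$records)
  expect_true(all(diff(s1$truth$membrane_order) > 0))
  expect_false(any(s1$truth$disrupted))
  # two levels mapped to identical order give identical expected well GP
  cfg0 <- calcium_series_config(calcium_levels = c(1, 1), seed = 5L,
                                wells_per_level = 1L,
                                noise_model = "none")
  s0 <- make_calcium_series(cfg0, default_basis())
  tab <- plate_gp_table(s0$records)
  expect_equal(tab$gp[1], tab$gp[2])
  expect_error(calcium_series_config(calcium_levels = numeric()),
               "non-empty")
})

test_that("disruption collapses brightness and fragments the ring", {
  cfg <- calcium_series_config(calcium_levels = c(1.5, 5), seed = 6L,
                               wells_per_level = 1L,
                               noise_model = "none")
  s <- make_calcium_series(cfg, default_basis(), images = TRUE)
  expect_identical(s$truth$disrupted, c(FALSE, TRUE))
  tot <- vapply(s$records$condition_mM |> unique(), function(lv)
    sum(s$records$intensity[s$records$condition_mM == lv]), numeric(1))
  expect_lt(tot[2], 0.5 * tot[1])
  ring_ok <- sum(s$images[[1]]$labels == 2L)
  ring_disrupted <- sum(s$images[[2]]$labels == 2L)
  expect_lt(ring_disrupted, ring_ok)
})
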