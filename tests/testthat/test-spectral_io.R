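test_that("channel_grid tiles detection ranges correctly", {
  g <- channel_grid(415, 691, 8.9)
  expect_length(g, 32L)            # the 32-channel confocal geometry
  expect_equal(g[1], 415)
  expect_equal(diff(g), rep(8.9, 31))
  expect_length(channel_grid(400, 500, 100), 1L)
  expect_length(channel_grid(405, 600, 1), 195L)
  expect_error(channel_grid(415, 691, 0), "interval")
  expect_error(channel_grid(691, 415, 8.9), "range_end")
})

test_that("lambda stacks round-trip through TIFF + sidecar", {
  ph <- small_phantom("poisson", seed = 2L)   # integer counts: exact in f32
  path <- withr::local_tempfile(fileext = ".tif")
  write_spectral_image(ph$image, path)
  back <- read_spectral_image(path)
  expect_identical(back$intensities, ph$image$intensities)
  expect_equal(back$channel_centers, ph$image$channel_centers)
  expect_equal(back$excitation, ph$image$excitation)
})

test_that("channels are reordered to ascending wavelength", {
  arr <- array(0, c(2, 2, 3))
  for (k in 1:3) arr[, , k] <- k * 10
  path <- withr::local_tempfile(fileext = ".tif")
  laurdanGP:::write_tiff(arr, path, "float32")
  # wavelengths supplied in descending page order
  img <- read_spectral_image(path, wavelengths = c(490, 465, 440))
  expect_equal(img$channel_centers, c(440, 465, 490))
  expect_equal(img$intensities[1, 1, ], c(30, 20, 10))
})

test_that("reader rejects malformed stacks", {
  ph <- small_phantom("none")
  path <- withr::local_tempfile(fileext = ".tif")
  write_spectral_image(ph$image, path)
  expect_error(read_spectral_image(path,
                 wavelengths = ph$image$channel_centers[-1]),
               "format error")
  expect_error(read_spectral_image(path,
                 wavelengths = rep(500, 32)), "duplicated")
  expect_error(read_spectral_image("no/such/file.tif"), "no such file")
  # sidecar with wrong count
  sc <- paste0(path, ".json")
  jsonlite::write_json(list(channel_centers = 1:31), sc)
  expect_error(read_spectral_image(path), "format error")
})

test_that("label maps round-trip", {
  ph <- small_phantom("none")
  p <- withr::local_tempfile(fileext = ".tif")
  write_label_map(ph$labels, p)
  expect_identical(read_label_map(p), ph$labels)
})

test_that("plate CSV round-trips and parses order-insensitively", {
  cfg <- calcium_series_config(calcium_levels = c(0.06, 1.5), seed = 3L,
                               wells_per_level = 1L)
  s <- make_calcium_series(cfg, default_basis())
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(s$records, path)
  back <- read_plate_csv(path)
  key <- function(d) d[order(d$well, d$flash, d$wavelength_nm), ]
  expect_equal(key(as.data.frame(back)),
               key(as.data.frame(s$records)),
               ignore_attr = TRUE)
  # shuffled rows parse to the same grouped records
  df <- utils::read.csv(path)
  set.seed(1)
  utils::write.csv(df[sample(nrow(df)), ], path, row.names = FALSE)
  expect_equal(as.data.frame(read_plate_csv(path)),
               as.data.frame(back), ignore_attr = TRUE)
  # a 25-flash well yields 25 spectra
  sp <- plate_spectra(back)
  expect_length(sp[[1]], 25L)
  expect_equal(attr(sp[[1]], "condition_mM"), 0.06)
})

test_that("plate reader rejects schema and value violations", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(well = "A1", flash = 1), path,
                   row.names = FALSE)
  expect_error(read_plate_csv(path), "missing plate CSV column")
  df <- data.frame(well = "A1", condition_mM = 1, flash = 1,
                   wavelength_nm = c(440, 490), intensity = c(-5, 10))
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_plate_csv(path), "negative")
  expect_warning(ok <- read_plate_csv(path, negative = "clamp"),
                 "clamping")
  expect_equal(ok$intensity, c(0, 10))
  df$intensity <- c(5, 10); df$flash <- 0
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_plate_csv(path), "flash")
})

test_that("GP maps write with sentinel and mask", {
  ph <- small_phantom("none")
  map <- compute_gp_map(ph$image, mode = "band_mean")
  p <- withr::local_tempfile(fileext = ".tif")
  write_gp_map(map, p)
  plane <- laurdanGP:::read_tiff(p)[, , 1]
  mask <- laurdanGP:::read_tiff(sub("\\.tif$", "_mask.tif", p))[, , 1]
  expect_equal(mask == 1, map$valid_mask, ignore_attr = TRUE)
  expect_true(all(plane[mask == 0] == -2))
  expect_equal(plane[mask == 1], map$gp[map$valid_mask],
               tolerance = 1e-6)
})
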