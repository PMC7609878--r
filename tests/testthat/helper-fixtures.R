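# Shared fixtures: one default basis, small phantoms sized so the whole
# suite stays fast. Everything is generated in code; no binary fixtures.

default_basis <- function() {
  if (is.null(.fixture_env$basis))
    .fixture_env$basis <- make_basis_spectra()
  .fixture_env$basis
}
.fixture_env <- new.env(parent = emptyenv())

small_phantom <- function(noise = "none", seed = 1L, membrane = 0.8,
                          interior = 0.3, size = 32L) {
  make_cell_image(
    cell_phantom_config(image_size = c(size, size), outer_radius = 12,
                        ring_thickness = 3, membrane_order = membrane,
                        interior_order = interior, brightness = 500,
                        background_level = 2, noise_model = noise,
                        seed = seed),
    default_basis())
}

# independent brute-force oracle for band intensities
brute_band_mean <- function(wl, intensity, center, halfwidth) {
  tot <- 0; n <- 0L
  for (i in seq_along(wl)) {
    if (wl[i] >= center - halfwidth && wl[i] <= center + halfwidth) {
      tot <- tot + intensity[i]; n <- n + 1L
    }
  }
  tot / n
}
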