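# Synthetic hyperspectral keratinocyte phantoms and calcium-series
# plate-reader data with known ground-truth membrane order. Pixel spectra
# are convex combinations of two solvatochromic basis states: a blue
# (ordered, tightly packed) emission near 440 nm and a red (disordered,
# fluid) emission near 490 nm. Ground truth is the ordered fraction phi,
# not a GP value, so recovered GP is a genuine pipeline output.

#' Two-state Laurdan basis spectra
#'
#' Builds the ordered (blue-shifted) and disordered (red-shifted) emission
#' bases on a common wavelength grid, each a unit-peak Gaussian profile.
#' The ordered basis must have higher band GP than the disordered one
#' whenever the peaks differ.
#'
#' @param grid wavelength grid (nm), strictly increasing.
#' @param ordered_peak peak of the ordered-state emission (nm).
#' @param disordered_peak peak of the disordered-state emission (nm).
#' @param width Gaussian standard width (nm), `> 0`.
#' @return an object of class `basis_spectra` with fields
#'   `ordered_spectrum`, `disordered_spectrum`, `gp_ordered`,
#'   `gp_disordered` (band GPs of the two bases).
#' @export
#' @examples
#' b <- make_basis_spectra()
#' b$gp_ordered > 0 && b$gp_disordered < 0
make_basis_spectra <- function(grid = channel_grid(415, 691, 8.9),
                               ordered_peak = 440, disordered_peak = 490,
                               width = 45) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (width <= 0) stop("width must be positive")
  rng <- range(grid)
  for (p in c(ordered_peak, disordered_peak))
    if (p < rng[1] || p > rng[2])
      stop(sprintf("peak %.1f nm outside grid range [%.1f, %.1f]",
                   p, rng[1], rng[2]))
  shape <- function(peak) exp(-(grid - peak)^2 / (2 * width^2))
  ord <- emission_spectrum(grid, shape(ordered_peak))
  dis <- emission_spectrum(grid, shape(disordered_peak))
  out <- structure(list(ordered_spectrum = ord, disordered_spectrum = dis,
                        ordered_peak = ordered_peak,
                        disordered_peak = disordered_peak, width = width),
                   class = "basis_spectra")
  out$gp_ordered <- gp_from_spectrum(ord)$gp
  out$gp_disordered <- gp_from_spectrum(dis)$gp
  if (ordered_peak < disordered_peak &&
      out$gp_ordered <= out$gp_disordered)
    stop("degenerate basis: ordered GP not above disordered GP")
  out
}

#' Mix the two basis states at a given ordered fraction
#'
#' The linear two-state model: `brightness * (phi * ordered +
#' (1 - phi) * disordered)`, noiseless.
#'
#' @param basis a [make_basis_spectra()] object.
#' @param order ordered fraction `phi` in `[0, 1]`.
#' @param brightness expected peak-scale photon count (counts, `>= 0`).
#' @return an [emission_spectrum()].
#' @export
mix_spectrum <- function(basis, order, brightness = 1) {
  stopifnot(inherits(basis, "basis_spectra"))
  if (!is.finite(order) || order < 0 || order > 1)
    stop("order must be in [0, 1]")
  if (brightness < 0) stop("brightness must be nonnegative")
  emission_spectrum(
    basis$ordered_spectrum$wavelength,
    brightness * (order * basis$ordered_spectrum$intensity +
                  (1 - order) * basis$disordered_spectrum$intensity))
}

#' Configuration for a two-compartment cell phantom
#'
#' Describes an annular plasma-membrane ring around a fluid interior,
#' mirroring the morphology resolved by spectral imaging of keratinocytes:
#' a tightly packed surface membrane over more fluid internal organelle
#' membranes.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param center ring center `c(row, col)`; default image center.
#' @param outer_radius outer ring radius (px).
#' @param ring_thickness radial thickness of the membrane ring (px).
#' @param interior_order ordered fraction of the cell interior.
#' @param membrane_order ordered fraction of the membrane ring; must be
#'   `>=` interior_order for a differentiating phantom.
#' @param brightness expected peak photon count per pixel (counts).
#' @param background_level flat background counts, `0 <= background <
#'   brightness`.
#' @param noise_model `"none"` or `"poisson"`.
#' @param seed integer RNG seed used when noise is requested.
#' @return a validated list of class `cell_phantom_config`.
#' @export
cell_phantom_config <- function(image_size = c(48, 48), center = NULL,
                                outer_radius = 18, ring_thickness = 3,
                                interior_order = 0.3, membrane_order = 0.8,
                                brightness = 500, background_level = 2,
                                noise_model = c("poisson", "none"),
                                seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(center)) center <- (image_size + 1) / 2
  if (membrane_order < interior_order)
    stop("membrane_order must be >= interior_order")
  for (phi in c(interior_order, membrane_order))
    if (phi < 0 || phi > 1) stop("order fractions must lie in [0, 1]")
  if (!(brightness > background_level && background_level >= 0))
    stop("need brightness > background_level >= 0")
  if (center[1] - outer_radius < 1 || center[1] + outer_radius > image_size[1] ||
      center[2] - outer_radius < 1 || center[2] + outer_radius > image_size[2])
    stop("ring does not fit within image bounds")
  if (ring_thickness <= 0 || ring_thickness >= outer_radius)
    stop("need 0 < ring_thickness < outer_radius")
  structure(list(image_size = as.integer(image_size), center = center,
                 outer_radius = outer_radius,
                 ring_thickness = ring_thickness,
                 interior_order = interior_order,
                 membrane_order = membrane_order, brightness = brightness,
                 background_level = background_level,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "cell_phantom_config")
}

#' Generate a hyperspectral cell phantom with ground-truth labels
#'
#' Every membrane-ring pixel carries the membrane-order mixture spectrum,
#' every interior pixel the interior-order mixture, and background pixels a
#' flat `background_level`. Poisson noise is applied channel-wise when
#' requested; identical seeds give identical images.
#'
#' @param config a [cell_phantom_config()].
#' @param basis a [make_basis_spectra()] object.
#' @return a list with `image` ([spectral_image()]), `labels` (`H x W`
#'   integer matrix: 0 background, 1 interior, 2 membrane) and `truth`
#'   (the generating orders and analytic per-class spectra).
#' @export
make_cell_image <- function(config = cell_phantom_config(),
                            basis = make_basis_spectra()) {
  stopifnot(inherits(config, "cell_phantom_config"),
            inherits(basis, "basis_spectra"))
  h <- config$image_size[1]; w <- config$image_size[2]
  grid <- basis$ordered_spectrum$wavelength
  nch <- length(grid)
  r <- sqrt(outer((seq_len(h) - config$center[1])^2,
                  (seq_len(w) - config$center[2])^2, `+`))
  labels <- matrix(0L, h, w)
  labels[r <= config$outer_radius] <- 1L
  labels[r <= config$outer_radius &
         r > config$outer_radius - config$ring_thickness] <- 2L
  spec_int <- mix_spectrum(basis, config$interior_order,
                           config$brightness)$intensity
  spec_mem <- mix_spectrum(basis, config$membrane_order,
                           config$brightness)$intensity
  spec_bg <- rep(config$background_level, nch)
  arr <- array(0, c(h, w, nch))
  for (k in seq_len(nch)) {
    plane <- matrix(spec_bg[k], h, w)
    plane[labels == 1L] <- spec_int[k]
    plane[labels == 2L] <- spec_mem[k]
    arr[, , k] <- plane
  }
  if (config$noise_model == "poisson") {
    set.seed(config$seed)
    arr[] <- stats::rpois(length(arr), lambda = arr)
  }
  img <- spectral_image(arr, grid, excitation = 405,
                        source_id = sprintf("phantom(seed=%d)", config$seed))
  list(image = img, labels = labels,
       truth = list(interior_order = config$interior_order,
                    membrane_order = config$membrane_order,
                    spectrum_interior = spec_int,
                    spectrum_membrane = spec_mem,
                    config = config))
}

#' Hill-type calcium-to-order mapping
#'
#' Monotone saturating map from extracellular calcium concentration (mM)
#' to the membrane ordered fraction phi:
#' `floor + (ceiling - floor) * c^h / (c^h + K^h)`.
#'
#' Defaults place the synthetic membrane GP near 0.18 at proliferative
#' calcium (0.06 mM) rising to about 0.27 at differentiating levels,
#' with the cytosolic population (order ~ 0.25, GP ~ -0.17) well
#' separated throughout - the qualitative picture the assay reports.
#'
#' @param calcium concentration(s), mM.
#' @param half_max half-saturation concentration K (mM).
#' @param steepness Hill coefficient h.
#' @param floor,ceiling phi at zero and saturating calcium.
#' @return ordered fraction(s) in `[floor, ceiling]`.
#' @export
calcium_order_map <- function(calcium, half_max = 0.5, steepness = 1.5,
                              floor = 0.80, ceiling = 0.97) {
  if (any(calcium < 0)) stop("calcium must be nonnegative")
  if (!(floor >= 0 && ceiling <= 1 && ceiling >= floor))
    stop("need 0 <= floor <= ceiling <= 1")
  ch <- calcium^steepness
  floor + (ceiling - floor) * ch / (ch + half_max^steepness)
}

#' Configuration for a synthetic calcium-switch series
#'
#' @param calcium_levels calcium concentrations (mM); the assay's tested
#'   range spans 0.06-5 mM.
#' @param half_max,steepness,floor,ceiling parameters of
#'   [calcium_order_map()].
#' @param disruption_threshold concentration (mM) at and above which cell
#'   integrity collapses: brightness drops and, in images, the membrane
#'   ring fragments.
#' @param interior_order fixed ordered fraction of the cytosolic fraction.
#' @param membrane_fraction signal fraction contributed by the plasma
#'   membrane in a whole-well (ensemble) spectrum.
#' @param wells_per_level,flashes_per_well replicate structure; plate
#'   readings average a minimum of 25 flashes per well.
#' @param brightness expected counts at peak per flash.
#' @param noise_model `"poisson"` or `"none"`.
#' @param seed integer RNG seed.
#' @return a validated list of class `calcium_series_config`.
#' @export
calcium_series_config <- function(calcium_levels = c(0.06, 0.3, 0.75, 1.5, 5),
                                  half_max = 0.5, steepness = 1.5,
                                  floor = 0.80, ceiling = 0.97,
                                  disruption_threshold = 5,
                                  interior_order = 0.25,
                                  membrane_fraction = 0.5,
                                  wells_per_level = 3L,
                                  flashes_per_well = 25L,
                                  brightness = 500,
                                  noise_model = c("poisson", "none"),
                                  seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (!length(calcium_levels)) stop("calcium_levels must be non-empty")
  if (any(calcium_levels < 0)) stop("calcium levels must be nonnegative")
  if (flashes_per_well < 1L) stop("need at least one flash per well")
  if (flashes_per_well < 25L)
    warning("flashes_per_well below the recommended minimum of 25")
  if (membrane_fraction < 0 || membrane_fraction > 1)
    stop("membrane_fraction must lie in [0, 1]")
  structure(list(calcium_levels = as.numeric(calcium_levels),
                 half_max = half_max, steepness = steepness, floor = floor,
                 ceiling = ceiling,
                 disruption_threshold = disruption_threshold,
                 interior_order = interior_order,
                 membrane_fraction = membrane_fraction,
                 wells_per_level = as.integer(wells_per_level),
                 flashes_per_well = as.integer(flashes_per_well),
                 brightness = brightness, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "calcium_series_config")
}

#' Generate a synthetic calcium-switch plate-reader series
#'
#' For each calcium level, generates `wells_per_level` wells of
#' `flashes_per_well` flash spectra on a 1-nm 405-600 nm grid. Each
#' noiseless flash spectrum is the two-population ensemble
#' `brightness * (f * mix(phi_mem(Ca)) + (1 - f) * mix(phi_interior))`;
#' at levels at or above the disruption threshold brightness collapses to
#' 20 percent. Poisson noise is applied per flash when requested.
#'
#' @param config a [calcium_series_config()].
#' @param basis a [make_basis_spectra()] object; its Gaussian shape
#'   parameters are re-evaluated on the plate-reader grid.
#' @param images if `TRUE`, also generate one cell phantom image per level
#'   (fragmented ring at disrupted levels).
#' @return a list with `records` (a `plate_records` data frame: columns
#'   `well`, `condition_mM`, `flash`, `wavelength_nm`, `intensity`),
#'   `truth` (per-level membrane order and disruption flag) and, when
#'   requested, `images`.
#' @export
make_calcium_series <- function(config = calcium_series_config(),
                                basis = make_basis_spectra(),
                                images = FALSE) {
  stopifnot(inherits(config, "calcium_series_config"))
  plate_grid <- channel_grid(405, 600, 1)
  pbasis <- make_basis_spectra(plate_grid, basis$ordered_peak,
                               basis$disordered_peak, basis$width)
  set.seed(config$seed)
  order_mem <- calcium_order_map(config$calcium_levels, config$half_max,
                                 config$steepness, config$floor,
                                 config$ceiling)
  disrupted <- config$calcium_levels >= config$disruption_threshold
  recs <- vector("list",
                 length(config$calcium_levels) * config$wells_per_level)
  idx <- 0L
  img_list <- list()
  for (i in seq_along(config$calcium_levels)) {
    bright <- config$brightness * if (disrupted[i]) 0.2 else 1
    noiseless <- config$membrane_fraction *
      mix_spectrum(pbasis, order_mem[i], bright)$intensity +
      (1 - config$membrane_fraction) *
      mix_spectrum(pbasis, config$interior_order, bright)$intensity
    for (wl in seq_len(config$wells_per_level)) {
      idx <- idx + 1L
      well_id <- sprintf("L%02dW%02d", i, wl)
      nflash <- config$flashes_per_well
      flat <- rep(noiseless, nflash)
      if (config$noise_model == "poisson")
        flat <- stats::rpois(length(flat), flat)
      recs[[idx]] <- data.frame(
        well = well_id, condition_mM = config$calcium_levels[i],
        flash = rep(seq_len(nflash), each = length(plate_grid)),
        wavelength_nm = rep(plate_grid, nflash), intensity = flat)
    }
    if (images) {
      cfg <- cell_phantom_config(
        membrane_order = order_mem[i],
        interior_order = min(config$interior_order, order_mem[i]),
        brightness = bright, noise_model = config$noise_model,
        seed = config$seed + i)
      ph <- make_cell_image(cfg, basis)
      if (disrupted[i]) {
        # fragmentation: knock out a random half of the ring pixels
        ring <- which(ph$labels == 2L)
        drop <- sample(ring, length(ring) %/% 2)
        for (k in seq_along(ph$image$channel_centers)) {
          plane <- ph$image$intensities[, , k]
          plane[drop] <- cfg$background_level
          ph$image$intensities[, , k] <- plane
        }
        ph$labels[drop] <- 0L
      }
      img_list[[i]] <- ph
    }
  }
  records <- do.call(rbind, recs)
  class(records) <- c("plate_records", class(records))
  out <- list(records = records,
              truth = data.frame(condition_mM = config$calcium_levels,
                                 membrane_order = order_mem,
                                 disrupted = disrupted))
  if (images) out$images <- img_list
  out
}
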