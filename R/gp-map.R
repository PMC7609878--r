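# Masked per-pixel GP maps. Background pixels (summed spectrum below an
# absolute count floor or below a quantile of the nonzero-pixel sums) and
# pixels whose spectral fit failed are invalid and excluded from every
# downstream statistic; they are never coerced to GP = 0.

.parse_mask_policy <- function(mask_policy) {
  if (is.list(mask_policy)) {
    defaults <- list(quantile = 0, floor = 0, rel_floor = 0)
    defaults[names(mask_policy)] <- mask_policy
    return(defaults)
  }
  if (is.character(mask_policy) && length(mask_policy) == 1L) {
    if (grepl("^quantile:", mask_policy))
      return(list(quantile = as.numeric(sub("^quantile:", "", mask_policy)),
                  floor = 0, rel_floor = 0))
    if (grepl("^intensity_threshold:", mask_policy))
      return(list(quantile = 0, rel_floor = 0,
                  floor = as.numeric(sub("^intensity_threshold:", "",
                                         mask_policy))))
  }
  stop("unrecognized mask_policy: ", deparse(mask_policy))
}

#' Compute a per-pixel GP map from a lambda stack
#'
#' For each foreground pixel the emission spectrum is reduced to a GP
#' value. `mode = "fit_eval"` (default) fits a gamma-variate curve per
#' pixel and evaluates it at 440/490 nm; `"nearest_channels"` uses the
#' observed intensities of the channels nearest 440/490 nm;
#' `"band_mean"` uses mean intensities over the 440/490 +/- 10 nm bands.
#' Identical spectra are fitted once (memoised), so noiseless phantoms
#' cost a handful of fits.
#'
#' @param image a [spectral_image()] whose grid covers both GP bands.
#' @param mask_policy `"quantile:q"` (pixels whose summed spectrum is
#'   below the q-quantile of nonzero pixel sums are background),
#'   `"intensity_threshold:t"` (absolute floor in counts), or a list with
#'   any of `quantile`, `floor` (absolute counts) and `rel_floor`
#'   (fraction of the brightest pixel's summed intensity). The default
#'   masks the dimmest 5 percent of nonzero pixels and everything below
#'   5 percent of the brightest pixel - a dim, flat detector background
#'   never reaches zero counts under photon noise, so a purely
#'   quantile-based mask would let it through as a spurious GP ~ 0
#'   population.
#' @param mode pixel GP statistic, see above.
#' @param bands band definition, see [gp_bands()].
#' @return an object of class `gp_map`: `gp` (`H x W`, `NA` where
#'   invalid), `valid_mask`, `fit_quality` (per-pixel RSS in fitting
#'   mode), `band_definition`, `mode`, `mask_policy`.
#' @export
compute_gp_map <- function(image,
                           mask_policy = list(quantile = 0.05, floor = 0,
                                              rel_floor = 0.05),
                           mode = c("fit_eval", "nearest_channels",
                                    "band_mean"),
                           bands = gp_bands()) {
  stopifnot(inherits(image, "spectral_image"))
  mode <- match.arg(mode)
  pol <- .parse_mask_policy(mask_policy)
  wl <- image$channel_centers
  for (b in bands)
    if (!any(wl >= b[1] - b[2] & wl <= b[1] + b[2]))
      stop(sprintf("image does not cover the %.0f +/- %.0f nm band",
                   b[1], b[2]))
  d <- dim(image$intensities)
  sums <- apply(image$intensities, c(1, 2), sum)
  nz <- sums[sums > 0]
  thr <- pol$floor
  if (length(nz) && pol$quantile > 0)
    thr <- max(thr, stats::quantile(nz, pol$quantile, names = FALSE))
  if (length(nz) && pol$rel_floor > 0)
    thr <- max(thr, pol$rel_floor * max(nz))
  valid <- sums > thr
  gp <- matrix(NA_real_, d[1], d[2])
  quality <- matrix(NA_real_, d[1], d[2])

  flat <- matrix(image$intensities, nrow = d[1] * d[2], ncol = d[3])
  idx <- which(valid)
  if (mode == "band_mean") {
    inb <- function(b) wl >= b[1] - b[2] & wl <= b[1] + b[2]
    i440 <- rowMeans(flat[idx, inb(bands$blue), drop = FALSE])
    i490 <- rowMeans(flat[idx, inb(bands$red), drop = FALSE])
    gp[idx] <- gp_index(i440, i490)
  } else if (mode == "nearest_channels") {
    c440 <- which.min(abs(wl - bands$blue[1]))
    c490 <- which.min(abs(wl - bands$red[1]))
    gp[idx] <- gp_index(flat[idx, c440], flat[idx, c490])
  } else {
    cache <- new.env(parent = emptyenv())
    for (p in idx) {
      key <- paste(flat[p, ], collapse = ",")
      hit <- get0(key, envir = cache, inherits = FALSE)
      if (is.null(hit)) {
        sp <- emission_spectrum(wl, flat[p, ])
        fit <- fit_gamma_variate(sp)
        val <- pixel_gp_from_fit(fit, "fit_eval", spectrum = sp,
                                 bands = bands)
        hit <- list(gp = val$gp, rss = fit$rss)
        assign(key, hit, envir = cache)
      }
      gp[p] <- hit$gp
      quality[p] <- hit$rss
    }
  }
  valid <- valid & !is.na(gp)
  gp[!valid] <- NA_real_
  structure(list(gp = gp, valid_mask = valid, fit_quality = quality,
                 band_definition = bands, mode = mode, mask_policy = pol),
            class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  v <- x$gp[x$valid_mask]
  cat(sprintf(
    "<gp_map: %d x %d px, %d valid (%.1f%%), mode %s, GP range [%.3f, %.3f]>\n",
    nrow(x$gp), ncol(x$gp), length(v),
    100 * length(v) / length(x$gp), x$mode,
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Valid GP values of a map
#'
#' @param map a [compute_gp_map()] result.
#' @return numeric vector of the valid pixels' GP values.
#' @export
gp_values <- function(map) {
  stopifnot(inherits(map, "gp_map"))
  map$gp[map$valid_mask]
}

.gp_lut <- function(n = 256L) {
  ramp <- grDevices::colorRamp(c("#0000B0", "#00A0FF", "#00D080",
                                 "#FFD000", "#FF3000"))
  ramp(seq(0, 1, length.out = n)) / 255
}

#' Render a GP map as a pseudo-colour RGB image
#'
#' Blue-to-red look-up table over the chosen GP range (blue = fluid/low
#' GP, red = ordered/high GP). Invalid pixels render neutral gray. The
#' range actually used is attached as the `lut_range` attribute, matching
#' the practice of annotating each image with the LUT bounds.
#'
#' @param map a [compute_gp_map()] result with at least one valid pixel
#'   when `lut_range = "data_minmax"`.
#' @param lut_range `"data_minmax"` (LUT spans the data's own min/max GP)
#'   or a numeric `c(lo, hi)` fixed range.
#' @return an `H x W x 3` array in `[0, 1]` with attribute `lut_range`.
#' @export
render_gp_map <- function(map, lut_range = "data_minmax") {
  stopifnot(inherits(map, "gp_map"))
  v <- gp_values(map)
  if (identical(lut_range, "data_minmax")) {
    if (!length(v)) stop("no valid pixels: cannot derive a data LUT range")
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * 1e-6
  } else {
    rng <- as.numeric(lut_range)
    if (length(rng) != 2L || rng[2] <= rng[1])
      stop("lut_range must be 'data_minmax' or c(lo, hi) with hi > lo")
  }
  lut <- .gp_lut()
  n <- nrow(lut)
  scaled <- (map$gp - rng[1]) / (rng[2] - rng[1])
  bin <- pmin(n, pmax(1L, 1L + as.integer(floor(scaled * (n - 1L) + 0.5))))
  out <- array(0.5, c(dim(map$gp), 3L))  # neutral gray background
  ok <- which(map$valid_mask)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[ok] <- lut[bin[ok], ch]
    out[, , ch] <- plane
  }
  attr(out, "lut_range") <- rng
  out
}

#' Write a rendered GP map to a PNG file
#'
#' @param rgb an array from [render_gp_map()].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_gp_render <- function(rgb, path) {
  grDevices::png(path, width = dim(rgb)[2], height = dim(rgb)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(path)
}
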