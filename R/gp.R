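# The general polarization (GP) index: GP = (I440 - I490) / (I440 + I490),
# bounded in [-1, 1]. Higher values mean tighter lipid lateral packing
# (lower fluidity). Band intensities are means over the 440 +/- 10 nm and
# 490 +/- 10 nm windows, so GP is invariant to how many channels fall in a
# band (1 nm plate-reader grids and 8.9 nm confocal grids are comparable).

#' Default GP band definition
#'
#' @return a list with `blue = c(center, halfwidth)` and `red` alike, in nm.
#' @export
gp_bands <- function() list(blue = c(440, 10), red = c(490, 10))

#' General polarization index
#'
#' `GP = (i440 - i490) / (i440 + i490)`. Vectorized; pairs with zero total
#' intensity yield `NA` (undefined GP — such pixels are masked invalid
#' downstream, never coerced to 0, because GP = 0 is a meaningful value).
#'
#' @param i440 intensity at the ordered (440 nm) band, `>= 0`.
#' @param i490 intensity at the fluid (490 nm) band, `>= 0`.
#' @return numeric vector of GP values in `[-1, 1]`, `NA` where undefined.
#' @export
#' @examples
#' gp_index(3, 1)  # 0.5
gp_index <- function(i440, i490) {
  if (any(i440 < 0, na.rm = TRUE) || any(i490 < 0, na.rm = TRUE))
    stop("band intensities must be nonnegative")
  tot <- i440 + i490
  out <- ifelse(tot > 0, (i440 - i490) / tot, NA_real_)
  # guard against rounding just outside the closed interval
  pmin(1, pmax(-1, out))
}

#' Mean intensity over a wavelength band
#'
#' @param spectrum an [emission_spectrum()].
#' @param center band center (nm).
#' @param halfwidth band half-width (nm); the band is the closed interval
#'   `[center - halfwidth, center + halfwidth]`.
#' @return mean intensity over the samples inside the band.
#' @export
band_intensity <- function(spectrum, center, halfwidth) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  inb <- spectrum$wavelength >= center - halfwidth &
         spectrum$wavelength <= center + halfwidth
  if (!any(inb))
    stop(sprintf("no spectral samples in band %.0f +/- %.0f nm",
                 center, halfwidth))
  mean(spectrum$intensity[inb])
}

#' GP of a single emission spectrum (plate-reader path)
#'
#' Computes band intensities at 440 +/- 10 and 490 +/- 10 nm (mean over
#' in-band samples) and forms the GP index.
#'
#' @param spectrum an [emission_spectrum()] covering both bands.
#' @param bands band definition, see [gp_bands()].
#' @return a list of class `gp_value` with `gp`, `i440`, `i490`.
#' @export
gp_from_spectrum <- function(spectrum, bands = gp_bands()) {
  i440 <- band_intensity(spectrum, bands$blue[1], bands$blue[2])
  i490 <- band_intensity(spectrum, bands$red[1], bands$red[2])
  structure(list(gp = gp_index(i440, i490), i440 = i440, i490 = i490),
            class = "gp_value")
}

#' @export
print.gp_value <- function(x, ...) {
  cat(sprintf("<gp_value: GP = %.4f (I440 = %.4g, I490 = %.4g)>\n",
              x$gp, x$i440, x$i490))
  invisible(x)
}
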