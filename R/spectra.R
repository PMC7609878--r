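#' Emission spectrum
#'
#' A paired wavelength/intensity vector for one pixel, well or basis state.
#' Wavelengths must be strictly increasing and intensities finite and
#' nonnegative.
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly
#'   increasing.
#' @param intensity numeric vector of intensities (a.u. or counts), same
#'   length, all finite and `>= 0`.
#' @return an object of class `emission_spectrum`.
#' @export
#' @examples
#' s <- emission_spectrum(seq(415, 691, by = 8.9),
#'                        dnorm(seq(415, 691, by = 8.9), 440, 45))
#' gp_from_spectrum(s)
emission_spectrum <- function(wavelength, intensity) {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity))
    stop("wavelength and intensity lengths differ")
  if (length(wavelength) < 1L) stop("empty spectrum")
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and nonnegative")
  structure(list(wavelength = wavelength, intensity = intensity),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum: %d samples, %.1f-%.1f nm, peak %.1f nm>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$wavelength[which.max(x$intensity)]))
  invisible(x)
}

#' Spectral image (lambda stack)
#'
#' An `H x W x C` intensity stack with per-channel center wavelengths.
#'
#' @param intensities numeric `H x W x C` array, finite and `>= 0`.
#' @param channel_centers length-`C` vector of channel center wavelengths
#'   (nm), strictly increasing.
#' @param excitation excitation wavelength (nm), metadata only.
#' @param pixel_size pixel size in micrometres, optional metadata.
#' @param source_id free-text identifier recorded in provenance.
#' @return an object of class `spectral_image`.
#' @export
spectral_image <- function(intensities, channel_centers, excitation = 405,
                           pixel_size = NA_real_, source_id = "") {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L)
    stop("intensities must be an H x W x C array")
  channel_centers <- as.numeric(channel_centers)
  if (dim(intensities)[3] != length(channel_centers))
    stop(sprintf("channel count mismatch: %d pages vs %d wavelengths",
                 dim(intensities)[3], length(channel_centers)))
  if (any(!is.finite(channel_centers)) || any(diff(channel_centers) <= 0))
    stop("channel_centers must be strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and nonnegative")
  structure(list(intensities = intensities,
                 channel_centers = channel_centers,
                 excitation = excitation, pixel_size = pixel_size,
                 source_id = source_id),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<spectral_image: %d x %d px, %d channels (%.1f-%.1f nm), ex %.0f nm>\n",
    d[1], d[2], d[3], min(x$channel_centers), max(x$channel_centers),
    x$excitation))
  invisible(x)
}

#' Extract one pixel's emission spectrum from a lambda stack
#'
#' @param image a [spectral_image()].
#' @param row,col pixel coordinates (1-based).
#' @return an [emission_spectrum()].
#' @export
pixel_spectrum <- function(image, row, col) {
  stopifnot(inherits(image, "spectral_image"))
  emission_spectrum(image$channel_centers, image$intensities[row, col, ])
}
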