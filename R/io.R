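# Lambda-stack images travel as multi-page TIFF (one page per channel)
# with a JSON sidecar carrying the channel center wavelengths and the
# excitation line; OME-style embedded metadata is out of scope, explicit
# wavelength vectors are accepted instead. Plate-reader data travel as
# plain CSV (comma-separated, header, decimal point).

#' Spectral channel grid
#'
#' Channel center wavelengths tiling `[range_start, range_end]` at a
#' fixed interval: the channel count is the smallest `n` with
#' `range_start + n * interval >= range_end`. The confocal default
#' 415-691 nm at 8.9 nm yields 32 channels.
#'
#' @param range_start,range_end detection range (nm), `end > start`.
#' @param interval channel spacing (nm), `> 0`.
#' @return numeric vector of channel centers.
#' @export
#' @examples
#' length(channel_grid(415, 691, 8.9))  # 32
channel_grid <- function(range_start, range_end, interval) {
  if (interval <= 0) stop("interval must be positive")
  if (range_end <= range_start) stop("range_end must exceed range_start")
  n <- ceiling((range_end - range_start) / interval - 1e-9)
  range_start + (seq_len(n) - 1L) * interval
}

#' Write a lambda stack as multi-page TIFF plus JSON sidecar
#'
#' @param image a [spectral_image()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @param sidecar sidecar path; default `paste0(path, ".json")`.
#' @param dtype TIFF sample type; `"float32"` by default, `"float64"`
#'   when lossless round-trip of non-integer intensities is required.
#' @return `path`, invisibly.
#' @export
write_spectral_image <- function(image, path,
                                 sidecar = paste0(path, ".json"),
                                 dtype = "float32") {
  stopifnot(inherits(image, "spectral_image"))
  write_tiff(image$intensities, path, dtype = dtype)
  meta <- list(channel_centers = image$channel_centers,
               excitation_nm = image$excitation,
               pixel_size_um = image$pixel_size,
               source_id = image$source_id)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a lambda stack from TIFF plus wavelength metadata
#'
#' Channels are reordered to ascending wavelength regardless of page
#' order on disk. The channel count on disk must match the wavelength
#' list exactly.
#'
#' @param path TIFF path.
#' @param wavelengths either `"sidecar"` (read `paste0(path, ".json")`)
#'   or an explicit numeric vector of channel center wavelengths.
#' @param sidecar sidecar path used when `wavelengths = "sidecar"`.
#' @return a validated [spectral_image()].
#' @export
read_spectral_image <- function(path, wavelengths = "sidecar",
                                sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such file: ", path)
  arr <- read_tiff(path)
  excitation <- 405; pixel_size <- NA_real_; source_id <- basename(path)
  if (identical(wavelengths, "sidecar")) {
    if (!file.exists(sidecar)) stop("missing wavelength sidecar: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    wl <- as.numeric(meta$channel_centers)
    if (!is.null(meta$excitation_nm)) excitation <- meta$excitation_nm
    if (!is.null(meta$pixel_size_um) && length(meta$pixel_size_um))
      pixel_size <- as.numeric(meta$pixel_size_um)
    if (!is.null(meta$source_id) && length(meta$source_id))
      source_id <- meta$source_id
  } else wl <- as.numeric(wavelengths)
  if (length(wl) != dim(arr)[3])
    stop(sprintf(
      "format error: %d TIFF pages but %d wavelengths supplied",
      dim(arr)[3], length(wl)))
  if (any(duplicated(wl)))
    stop("format error: duplicated channel wavelengths")
  ord <- order(wl)
  spectral_image(arr[, , ord, drop = FALSE], wl[ord],
                 excitation = excitation, pixel_size = pixel_size,
                 source_id = source_id)
}

#' Write a ground-truth label map as single-page integer TIFF
#'
#' @param labels integer matrix (0 background, 1 interior, 2 membrane).
#' @param path output path.
#' @export
write_label_map <- function(labels, path) {
  write_tiff(array(labels, c(dim(labels), 1L)), path, dtype = "uint8")
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path TIFF path.
#' @return integer matrix.
#' @export
read_label_map <- function(path) {
  arr <- read_tiff(path)
  matrix(as.integer(arr[, , 1]), dim(arr)[1], dim(arr)[2])
}

#' Write a GP map (values plus validity mask) as TIFF
#'
#' The GP plane is 32-bit float with invalid pixels stored as the
#' sentinel `-2` (outside the GP range); the mask is a uint8 page written
#' alongside.
#'
#' @param map a [compute_gp_map()] result.
#' @param path output path for the GP plane; the mask goes to
#'   `sub(".tif", "_mask.tif", path)` (or `paste0(path, "_mask")`).
#' @export
write_gp_map <- function(map, path) {
  stopifnot(inherits(map, "gp_map"))
  plane <- map$gp
  plane[!map$valid_mask] <- -2
  write_tiff(array(plane, c(dim(plane), 1L)), path, dtype = "float32")
  mask_path <- if (grepl("\\.tif{1,2}$", path))
    sub("(\\.tif{1,2})$", "_mask\\1", path) else paste0(path, "_mask")
  write_tiff(array(map$valid_mask + 0, c(dim(plane), 1L)), mask_path,
             dtype = "uint8")
  invisible(path)
}

.plate_columns <- c("well", "condition_mM", "flash", "wavelength_nm",
                    "intensity")

#' Write plate-reader records to CSV
#'
#' @param records a `plate_records` data frame (columns `well`,
#'   `condition_mM`, `flash`, `wavelength_nm`, `intensity`).
#' @param path output CSV path.
#' @export
write_plate_csv <- function(records, path) {
  stopifnot(all(.plate_columns %in% names(records)))
  utils::write.csv(records[, .plate_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read plate-reader records from CSV
#'
#' Validates the schema and every flash spectrum (strictly increasing
#' wavelengths, nonnegative intensities). Rows may appear in any order;
#' records are sorted by (well, flash, wavelength).
#'
#' @param path CSV path with columns `well`, `condition_mM`, `flash`,
#'   `wavelength_nm`, `intensity`.
#' @param negative how to treat negative intensities: `"error"`
#'   (default) or `"clamp"` to zero with a warning.
#' @return a `plate_records` data frame.
#' @export
read_plate_csv <- function(path, negative = c("error", "clamp")) {
  negative <- match.arg(negative)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.plate_columns, names(df))
  if (length(missing))
    stop("format error: missing plate CSV column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) stop("empty plate file: ", path)
  if (any(df$intensity < 0)) {
    if (negative == "error")
      stop("validation error: negative intensities in ", path)
    warning("clamping ", sum(df$intensity < 0),
            " negative intensities to zero")
    df$intensity[df$intensity < 0] <- 0
  }
  if (any(df$flash < 1)) stop("validation error: flash index < 1")
  df <- df[order(df$well, df$flash, df$wavelength_nm), .plate_columns]
  rownames(df) <- NULL
  by_flash <- split(df$wavelength_nm, interaction(df$well, df$flash,
                                                  drop = TRUE))
  for (wl in by_flash)
    if (any(diff(wl) <= 0))
      stop("validation error: non-increasing wavelengths within a flash")
  class(df) <- c("plate_records", class(df))
  df
}

#' Split plate records into per-well, per-flash emission spectra
#'
#' @param records a `plate_records` data frame.
#' @return nested list: `spectra[[well]][[flash]]` is an
#'   [emission_spectrum()]; each well element carries its condition as the
#'   `condition_mM` attribute.
#' @export
plate_spectra <- function(records) {
  stopifnot(all(.plate_columns %in% names(records)))
  out <- list()
  for (w in unique(records$well)) {
    sub <- records[records$well == w, ]
    flashes <- lapply(split(sub, sub$flash), function(d)
      emission_spectrum(d$wavelength_nm, d$intensity))
    attr(flashes, "condition_mM") <- sub$condition_mM[1]
    out[[w]] <- flashes
  }
  out
}
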