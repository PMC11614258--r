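#' Hyperspectral data-cube
#'
#' A `hypercube` wraps a 3-D array of non-negative radiance or reflectance
#' values indexed `(line, sample, band)` together with the band-center
#' wavelength grid (nm) and free-form header metadata. Whatever the on-disk
#' interleave, in memory the layout is always `(line, sample, band)`. Pixel
#' coordinates are 1-based `(row = line, col = sample)` throughout the
#' package.
#'
#' Negative sensor values are physically impossible for radiance and are
#' clamped to zero on construction; the count of clamped values is reported
#' via a message.
#'
#' @param data 3-D numeric array, dimensions `(lines, samples, bands)`.
#' @param wavelengths Strictly increasing numeric vector of band centers in
#'   nm, length equal to `dim(data)[3]`.
#' @param meta Named list of free-form header entries.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array (line, sample, band)",
          class = "avicube_error_format")
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3]) {
    abort(sprintf(
      "wavelength count (%d) does not match band dimension (%d)",
      length(wavelengths), dim(data)[3]), class = "avicube_error_format")
  }
  if (anyNA(wavelengths) || is.unsorted(wavelengths, strictly = TRUE)) {
    abort("wavelengths must be strictly increasing and non-missing",
          class = "avicube_error_format")
  }
  n_neg <- sum(data < 0, na.rm = TRUE)
  if (n_neg > 0) {
    data[data < 0] <- 0
    inform(sprintf("clamped %d negative value(s) to 0", n_neg),
           class = "avicube_clamped")
  }
  structure(
    list(data = data, wavelengths = wavelengths, meta = meta),
    class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d lines x %d samples x %d bands (%.1f-%.1f nm)\n",
    d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# Index of the band nearest a wavelength; ties break toward the lower band.
nearest_band <- function(wavelengths, wavelength_nm) {
  d <- abs(wavelengths - wavelength_nm)
  which(d <= min(d) + 1e-12)[1]
}

band_spacing <- function(wavelengths) {
  if (length(wavelengths) < 2) return(Inf)
  mean(diff(wavelengths))
}

#' Extract a single-band image from a cube
#'
#' Returns the band whose center wavelength is nearest the request; exact
#' midpoints between two bands resolve to the lower wavelength.
#'
#' @param cube A [hypercube].
#' @param wavelength_nm Requested wavelength (nm). Must lie within the
#'   cube's wavelength span extended by half a band spacing.
#' @return A list of class `band_image` with elements `values`
#'   (lines x samples matrix) and `wavelength` (the band center actually
#'   selected).
#' @export
slice_band <- function(cube, wavelength_nm) {
  wl <- cube$wavelengths
  half <- band_spacing(wl) / 2
  if (wavelength_nm < min(wl) - half || wavelength_nm > max(wl) + half) {
    abort(sprintf(
      "wavelength %.1f nm outside cube range [%.1f, %.1f] nm",
      wavelength_nm, min(wl), max(wl)), class = "avicube_error_range")
  }
  b <- nearest_band(wl, wavelength_nm)
  structure(list(values = cube$data[, , b], wavelength = wl[b]),
            class = "band_image")
}

#' Render an RGB composite from three band slices
#'
#' Stacks the band slices nearest the three requested wavelengths (R, G, B
#' order). Values are assumed to be reflectance in roughly `[0, 1]`; when
#' `rescale_percentile` is given the stack is first divided by that
#' percentile of its values so displays of radiance cubes fill the range.
#' The brighten factor is applied last and the result clipped to `[0, 1]`
#' (museum-specimen renders are commonly brightened ~300 % for display).
#'
#' @param cube A [hypercube].
#' @param wavelengths_nm Length-3 numeric, default `c(600, 550, 425)`.
#' @param brighten Multiplicative brightness factor, default 1.
#' @param rescale_percentile Optional percentile (0-1] used to normalise the
#'   stack before brightening; `NULL` (default) leaves values as stored.
#' @return A `lines x samples x 3` array with values in `[0, 1]`.
#' @export
render_rgb <- function(cube, wavelengths_nm = c(600, 550, 425), brighten = 1,
                       rescale_percentile = NULL) {
  if (length(wavelengths_nm) != 3) {
    abort("`wavelengths_nm` must have length 3 (R, G, B)",
          class = "avicube_error_format")
  }
  chans <- lapply(wavelengths_nm, function(w) slice_band(cube, w)$values)
  img <- array(unlist(chans, use.names = FALSE),
               dim = c(dim(cube$data)[1:2], 3L))
  if (!is.null(rescale_percentile)) {
    ref <- quantile(img, probs = rescale_percentile, na.rm = TRUE, names = FALSE)
    if (ref > 0) img <- img / ref
  }
  img <- img * brighten
  img[img > 1] <- 1
  img[img < 0] <- 0
  img
}
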