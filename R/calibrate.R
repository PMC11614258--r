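# Radiance -> reflectance calibration: a bright-image flat-field removes
# across-field illumination non-uniformity, then division by the in-scene
# white standard's median spectrum converts to reflectance.

#' Flat-field a cube against a bright reference image
#'
#' Push-broom acquisition illuminates one sensor line at a time, so
#' illumination varies across samples (columns) and bands but not lines.
#' The bright image (a uniform white target filling the field of view) is
#' averaged over its lines, giving one reference spectrum per column; every
#' pixel spectrum of `cube` is divided by its column's reference.
#'
#' Bands where the reference is zero cannot be corrected: they are set to
#' `NA` and counted in a message.
#'
#' @param cube A [hypercube] of radiance.
#' @param bright A [hypercube] of the bright image; must match `cube` in
#'   samples and bands (line count may differ).
#' @return A flat-fielded [hypercube]; `meta$flat_fielded` is set.
#' @export
flat_field <- function(cube, bright) {
  stopifnot(inherits(cube, "hypercube"), inherits(bright, "hypercube"))
  dc <- dim(cube$data); db <- dim(bright$data)
  if (dc[2] != db[2] || dc[3] != db[3]) {
    abort(sprintf(
      "bright image (%d samples x %d bands) does not match cube (%d x %d)",
      db[2], db[3], dc[2], dc[3]), class = "avicube_error_shape")
  }
  ref <- apply(bright$data, c(2, 3), mean)     # samples x bands
  n_zero <- sum(ref == 0)
  if (n_zero > 0) {
    ref[ref == 0] <- NA_real_
    inform(sprintf(
      "bright reference contains %d zero entrie(s); affected bands set to NA",
      n_zero), class = "avicube_flatfield_zeros")
  }
  out <- cube$data / rep(ref, each = dc[1])
  meta <- cube$meta
  meta$flat_fielded <- TRUE
  hypercube(out, cube$wavelengths, meta = meta)
}

#' Median spectrum of the reflectance-standard region
#'
#' @param cube A [hypercube].
#' @param mask Logical (or 0/1) matrix, `lines x samples`, `TRUE` over the
#'   standard.
#' @return Tibble with columns `wavelength`, `reflectance` (the per-band
#'   median over masked pixels).
#' @export
standard_spectrum <- function(cube, mask) {
  mask <- check_mask(mask, dim(cube$data)[1:2])
  if (!any(mask)) {
    abort("standard mask is empty", class = "avicube_error_value")
  }
  idx <- which(mask)
  d <- dim(cube$data)
  px <- matrix(cube$data, nrow = d[1] * d[2])[idx, , drop = FALSE]
  tibble(wavelength = cube$wavelengths, reflectance = colwise_median(px))
}

check_mask <- function(mask, dims) {
  if (!is.matrix(mask)) {
    abort("mask must be a matrix", class = "avicube_error_format")
  }
  if (!all(dim(mask) == dims)) {
    abort(sprintf("mask is %d x %d but image is %d x %d",
                  nrow(mask), ncol(mask), dims[1], dims[2]),
          class = "avicube_error_value")
  }
  mask <- mask != 0
  mask[is.na(mask)] <- FALSE
  mask
}

#' Convert sampled spectra to reflectance via the white standard
#'
#' Elementwise division by the standard's median spectrum, multiplied by the
#' standard's nominal reflectance. The default `nominal = 1` reproduces the
#' common practice of dividing by a 99 % Spectralon standard without further
#' correction; pass `nominal = 0.99` for the physically exact scaling.
#' Values above 1 can legitimately occur (specular highlights) and are kept;
#' values above `flag_above` trigger a message.
#'
#' @param sample Either a long spectrum tibble (`wavelength`, `reflectance`)
#'   or a wide sample-set tibble with `wl_<nm>` columns.
#' @param standard Long spectrum tibble from [standard_spectrum()], on the
#'   same wavelength grid.
#' @param nominal Nominal reflectance of the standard, in (0, 1].
#' @param flag_above Threshold above which calibrated values are reported.
#' @return Same shape as `sample`, calibrated. Bands where the standard is
#'   zero become `NA` (counted in a message).
#' @export
to_reflectance <- function(sample, standard, nominal = 1, flag_above = 2) {
  check_spectrum_tbl(standard, "standard")
  if (!(nominal > 0 && nominal <= 1)) {
    abort("`nominal` must lie in (0, 1]", class = "avicube_error_value")
  }
  denom <- standard$reflectance
  n_zero <- sum(denom == 0, na.rm = TRUE)
  if (n_zero > 0) {
    denom[denom == 0] <- NA_real_
    inform(sprintf("standard spectrum has %d zero band(s); set to NA", n_zero),
           class = "avicube_standard_zeros")
  }
  wide <- any(is_wl_col(names(sample)))
  if (wide) {
    m <- spectra_matrix(sample)
    wl <- attr(m, "wavelengths")
    match_grid(wl, standard$wavelength)
    out <- sweep(m, 2, denom, `/`) * nominal
    res <- set_spectra(sample, out, wl)
  } else {
    check_spectrum_tbl(sample, "sample")
    match_grid(sample$wavelength, standard$wavelength)
    res <- mutate(sample, reflectance = .data$reflectance / denom * nominal)
  }
  vals <- if (wide) spectra_matrix(res) else res$reflectance
  n_hi <- sum(vals > flag_above, na.rm = TRUE)
  if (n_hi > 0) {
    inform(sprintf("%d calibrated value(s) exceed %.2f (specular highlights?)",
                   n_hi, flag_above), class = "avicube_high_reflectance")
  }
  res
}

match_grid <- function(a, b) {
  if (length(a) != length(b) || max(abs(a - b)) > 1e-6) {
    abort("sample and standard wavelength grids differ",
          class = "avicube_error_value")
  }
  invisible(TRUE)
}
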