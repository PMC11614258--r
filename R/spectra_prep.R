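# Spectral preprocessing: piecewise-linear interpolation onto a 1 nm grid,
# Savitzky-Golay smoothing (window 45 nm, order 2 by default), and
# ultraviolet extrapolation down to 300 nm by extending the leftmost segment
# of a monotone (shape-preserving) cubic Hermite interpolant.

prep_stage <- function(x) attr(x, "prep_stage") %||% "raw"

set_stage <- function(x, stage) { attr(x, "prep_stage") <- stage; x }

apply_spectra <- function(x, f, new_wl = NULL) {
  wide <- any(is_wl_col(names(x)))
  if (wide) {
    m <- spectra_matrix(x)
    wl <- attr(m, "wavelengths")
    out <- t(apply(m, 1, function(v) f(wl, v)))
    set_spectra(x, out, new_wl %||% wl)
  } else {
    check_spectrum_tbl(x)
    tibble(wavelength = new_wl %||% x$wavelength,
           reflectance = f(x$wavelength, x$reflectance))
  }
}

#' Interpolate spectra onto an integer 1 nm grid
#'
#' Piecewise-linear interpolation onto `lo:hi` nm (default 325-700, the
#' wavelength range over which near-UV hyperspectral imagers are reliably
#' sensitive). No extrapolation: the source grid must span the target range.
#'
#' @param x A wide sample-set tibble (`wl_<nm>` columns) or a long spectrum
#'   tibble (`wavelength`, `reflectance`).
#' @param lo,hi Target range in nm (inclusive).
#' @return Same shape as `x`, on the `lo:hi` 1 nm grid.
#' @export
interpolate_1nm <- function(x, lo = 325, hi = 700) {
  grid <- seq(lo, hi, by = 1)
  wl0 <- if (any(is_wl_col(names(x)))) wavelengths_of(x) else x$wavelength
  if (min(wl0) > lo || max(wl0) < hi) {
    abort(sprintf(
      "source grid [%.1f, %.1f] does not cover requested [%d, %d] nm",
      min(wl0), max(wl0), lo, hi), class = "avicube_error_coverage")
  }
  out <- apply_spectra(x, function(wl, v) approx(wl, v, xout = grid)$y,
                       new_wl = grid)
  set_stage(out, "interpolated")
}

#' Savitzky-Golay smoothing of spectra
#'
#' Least-squares local polynomial smoothing. On a 1 nm grid the nm window
#' maps directly to filter points (45 nm = 45 points, odd). Edges are
#' handled by fitting the polynomial to the truncated window, so constants
#' and (for `polyorder = 2`) quadratics pass through unchanged everywhere.
#'
#' @param x Wide or long spectra on a uniform 1 nm grid.
#' @param window_nm Filter window in nm (odd number of points; default 45).
#' @param polyorder Polynomial order (default 2).
#' @return Smoothed spectra, same shape and grid.
#' @export
smooth_spectra <- function(x, window_nm = 45, polyorder = 2) {
  n_pts <- as.integer(round(window_nm))
  if (n_pts %% 2 == 0) n_pts <- n_pts + 1L
  wl0 <- if (any(is_wl_col(names(x)))) wavelengths_of(x) else x$wavelength
  if (max(abs(diff(wl0) - 1)) > 1e-9) {
    abort("spectra must be on a uniform 1 nm grid (run interpolate_1nm first)",
          class = "avicube_error_value")
  }
  if (n_pts > length(wl0)) {
    abort(sprintf("window (%d points) exceeds spectrum length (%d)",
                  n_pts, length(wl0)), class = "avicube_error_value")
  }
  out <- apply_spectra(x, function(wl, v)
    signal::sgolayfilt(v, p = polyorder, n = n_pts))
  set_stage(out, "smoothed")
}

# Monotone cubic Hermite (Fritsch-Carlson) fit on [fit_lo, hi]; the leftmost
# cubic segment is evaluated on the extrapolation range.
extrap_one <- function(wl, v, grid_ext, fit_window) {
  keep <- wl >= fit_window[1] & wl <= fit_window[2]
  f <- splinefun(wl[keep], v[keep], method = "monoH.FC")
  ext <- f(grid_ext)
  cap <- 1.5 * max(v, na.rm = TRUE)
  pmin(pmax(ext, 0), cap)
}

#' Extrapolate reflectance into the near ultraviolet
#'
#' Avian vision extends to 300 nm but near-UV imagers are noise-limited
#' below 325 nm. A shape-preserving (monotone-in-segments) cubic Hermite
#' interpolant is fitted to the smoothed spectrum on 325-700 nm and its
#' leftmost cubic segment evaluated on `lo`-324 nm. Extrapolated values are
#' clamped to `[0, 1.5 x max(R)]` to stay physical. The result is
#' continuous with the value at 325 nm.
#'
#' @param x Wide or long spectra on the 325-700 nm 1 nm grid (smoothed).
#' @param lo Lower edge of the extrapolated range (default 300).
#' @param fit_window Range (nm) the interpolant is fitted to
#'   (default `c(325, 700)`).
#' @return Spectra on the `lo`-700 nm grid; attribute
#'   `"extrapolated_below"` records the cut-off.
#' @export
extrapolate_uv <- function(x, lo = 300, fit_window = c(325, 700)) {
  wl0 <- if (any(is_wl_col(names(x)))) wavelengths_of(x) else x$wavelength
  if (abs(min(wl0) - fit_window[1]) > 1e-9 || max(wl0) < fit_window[2]) {
    abort(sprintf("expected spectra starting at %g nm and covering %g nm",
                  fit_window[1], fit_window[2]),
          class = "avicube_error_coverage")
  }
  grid_ext <- seq(lo, fit_window[1] - 1, by = 1)
  new_wl <- c(grid_ext, wl0)
  out <- apply_spectra(x, function(wl, v)
    c(extrap_one(wl, v, grid_ext, fit_window), v), new_wl = new_wl)
  out <- set_stage(out, "extrapolated")
  attr(out, "extrapolated_below") <- fit_window[1]
  out
}

#' Full spectral preprocessing chain
#'
#' [interpolate_1nm()] then [smooth_spectra()] then [extrapolate_uv()]:
#' output is exactly the 300-700 nm 1 nm grid (401 points).
#'
#' @inheritParams interpolate_1nm
#' @inheritParams smooth_spectra
#' @param uv_lo Lower edge of UV extrapolation (default 300).
#' @return Preprocessed spectra on 300-700 nm.
#' @export
prep_spectra <- function(x, lo = 325, hi = 700, window_nm = 45, polyorder = 2,
                         uv_lo = 300) {
  x %>%
    interpolate_1nm(lo = lo, hi = hi) %>%
    smooth_spectra(window_nm = window_nm, polyorder = polyorder) %>%
    extrapolate_uv(lo = uv_lo, fit_window = c(lo, hi))
}
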