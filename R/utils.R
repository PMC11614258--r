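# Shared helpers for the wide "sample set" tibble layout: metadata columns
# followed by one reflectance column per band, named wl_<nm>.

wl_name <- function(wl) {
  paste0("wl_", format(wl, trim = TRUE, scientific = FALSE, digits = 12))
}

is_wl_col <- function(nm) grepl("^wl_[0-9]", nm)

#' Wavelengths encoded in a sample-set tibble
#'
#' Sample sets store one column per band, named `wl_<nm>`. This returns the
#' numeric wavelength grid in column order.
#'
#' @param x A sample-set tibble (or anything with names).
#' @return Numeric vector of wavelengths in nm.
#' @export
wavelengths_of <- function(x) {
  nm <- names(x)[is_wl_col(names(x))]
  as.numeric(sub("^wl_", "", nm))
}

#' Extract the spectra matrix from a sample set
#'
#' @param x A sample-set tibble with `wl_<nm>` columns.
#' @return A numeric matrix (one row per sample) whose columns are bands;
#'   the wavelength grid is attached as attribute `"wavelengths"`.
#' @export
spectra_matrix <- function(x) {
  keep <- is_wl_col(names(x))
  if (!any(keep)) {
    abort("no `wl_<nm>` spectra columns found", class = "avicube_error_format")
  }
  m <- as.matrix(x[, keep, drop = FALSE])
  dimnames(m) <- list(NULL, names(x)[keep])
  attr(m, "wavelengths") <- as.numeric(sub("^wl_", "", colnames(m)))
  m
}

# Rebuild a sample set from metadata + a spectra matrix on a (new) grid.
set_spectra <- function(x, m, wavelengths) {
  meta <- x[, !is_wl_col(names(x)), drop = FALSE]
  colnames(m) <- wl_name(wavelengths)
  dplyr::bind_cols(as_tibble(meta), as_tibble(m))
}

# Long (wavelength, reflectance) tibble -> checked numeric pieces.
check_spectrum_tbl <- function(spec, arg = "spec") {
  if (!is.data.frame(spec) || !all(c("wavelength", "reflectance") %in% names(spec))) {
    abort(paste0("`", arg, "` must be a tibble with columns wavelength, reflectance"),
          class = "avicube_error_format")
  }
  if (is.unsorted(spec$wavelength, strictly = TRUE)) {
    abort(paste0("`", arg, "`: wavelengths must be strictly increasing"),
          class = "avicube_error_format")
  }
  spec
}

# Per-band median over the rows of a pixel x band matrix.
colwise_median <- function(m) apply(m, 2, median)

`%||%` <- function(a, b) if (is.null(a)) b else a
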