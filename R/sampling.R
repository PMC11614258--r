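# Uniform-grid patch sampling: lay a square lattice over each patch mask,
# spacing chosen so the number of in-mask lattice points approximates a
# target (equalising sample counts across patches and specimens), then
# extract a windowed-median spectrum at each location.

#' Read / write binary patch masks as PNG
#'
#' Masks travel as 8-bit PNG label images: any non-zero pixel is inside the
#' mask. `read_mask_png` returns a logical `lines x samples` matrix.
#'
#' @param path PNG file path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' @rdname read_mask_png
#' @param mask Logical matrix to write.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

grid_count <- function(mask, spacing, bbox) {
  off <- spacing / 2
  rows <- unique(round(seq(bbox[1] + off, bbox[2], by = spacing)))
  cols <- unique(round(seq(bbox[3] + off, bbox[4], by = spacing)))
  rows <- rows[rows >= bbox[1] & rows <= bbox[2]]
  cols <- cols[cols >= bbox[3] & cols <= bbox[4]]
  if (!length(rows) || !length(cols)) {
    return(data.frame(row = integer(), col = integer()))
  }
  pts <- expand.grid(row = rows, col = cols)
  inside <- mask[cbind(pts$row, pts$col)]
  pts[inside, , drop = FALSE]
}

#' Uniform grid of sampling locations over a mask
#'
#' Centers of a square lattice intersected with the mask. The spacing is
#' searched deterministically (starting from `floor(sqrt(area / target_n))`,
#' stepping by 1) until the returned count is within ±10 % of `target_n`;
#' if no spacing achieves that, the closest achievable count is used, ties
#' resolved toward the smaller spacing (more samples). `target_n = 1`
#' returns the in-mask pixel nearest the mask centroid.
#'
#' @param mask Logical `lines x samples` matrix.
#' @param target_n Desired number of locations (>= 1).
#' @return Tibble with columns `row`, `col` (1-based pixel coordinates) and
#'   attribute `"spacing"`.
#' @export
grid_locations <- function(mask, target_n) {
  mask <- mask != 0
  area <- sum(mask)
  if (area < 1) abort("mask is empty", class = "avicube_error_value")
  if (target_n < 1) abort("`target_n` must be >= 1", class = "avicube_error_value")
  ij <- which(mask, arr.ind = TRUE)
  if (target_n == 1) {
    ctr <- colMeans(ij)
    d2 <- (ij[, 1] - ctr[1])^2 + (ij[, 2] - ctr[2])^2
    best <- order(d2, ij[, 1], ij[, 2])[1]
    out <- tibble(row = unname(ij[best, 1]), col = unname(ij[best, 2]))
    attr(out, "spacing") <- NA_integer_
    return(out)
  }
  bbox <- c(min(ij[, 1]), max(ij[, 1]), min(ij[, 2]), max(ij[, 2]))
  s_max <- max(bbox[2] - bbox[1], bbox[4] - bbox[3], 1L)
  s0 <- max(1L, min(s_max, floor(sqrt(area / target_n))))
  tol <- 0.1 * target_n
  best_s <- NA_real_; best_err <- Inf
  try_spacing <- function(s) {
    cnt <- nrow(grid_count(mask, s, bbox))
    if (cnt < 1) return(FALSE)
    err <- abs(cnt - target_n)
    # strict < keeps the first (smaller) spacing on ties
    if (err < best_err) { best_err <<- err; best_s <<- s }
    err <= tol
  }
  done <- FALSE
  for (step in 0:s_max) {
    for (s in unique(c(s0 - step, s0 + step))) {
      if (s < 1 || s > s_max) next
      if (try_spacing(s)) { done <- TRUE; break }
    }
    if (done) break
  }
  if (!done && !is.na(best_s)) {
    # integer spacings bracket but miss the tolerance: refine fractionally
    for (s in seq(max(1, best_s - 1), min(s_max, best_s + 1), by = 0.05)) {
      if (try_spacing(s)) break
    }
  }
  if (is.na(best_s)) {
    abort("mask smaller than one sampling window", class = "avicube_error_value")
  }
  pts <- grid_count(mask, best_s, bbox)
  out <- tibble(row = pts$row, col = pts$col)
  attr(out, "spacing") <- best_s
  out
}

window_bounds <- function(center, w, n) {
  lo <- center - floor((w - 1) / 2)
  hi <- lo + w - 1
  c(max(1L, lo), min(n, hi))
}

#' Extract a windowed-median sample spectrum
#'
#' The per-band median over a square pixel window (default 10 x 10, i.e.
#' 100 pixels on interior locations) centered at `location`; the window is
#' truncated, not discarded, at image edges. The median makes single noisy
#' or saturated pixels inconsequential.
#'
#' @param cube A [hypercube].
#' @param location Length-2 integer `(row, col)`, 1-based.
#' @param window Window side length in pixels (default 10).
#' @return Tibble with columns `wavelength`, `reflectance`.
#' @export
extract_sample <- function(cube, location, window = 10) {
  d <- dim(cube$data)
  r <- as.integer(location[[1]]); c <- as.integer(location[[2]])
  if (r < 1 || r > d[1] || c < 1 || c > d[2]) {
    abort(sprintf("location (%d, %d) outside image %d x %d", r, c, d[1], d[2]),
          class = "avicube_error_range")
  }
  rb <- window_bounds(r, window, d[1])
  cb <- window_bounds(c, window, d[2])
  px <- cube$data[rb[1]:rb[2], cb[1]:cb[2], , drop = FALSE]
  m <- matrix(px, nrow = prod(dim(px)[1:2]))
  tibble(wavelength = cube$wavelengths, reflectance = colwise_median(m))
}

#' Build a labelled sample set from a cube and patch masks
#'
#' For every patch mask: grid the mask, drop locations whose sampling window
#' overlaps the white-standard region, extract windowed-median spectra and
#' calibrate them against the standard's median spectrum. Rows are labelled
#' with the supplied species / specimen / view and the patch name.
#'
#' @param cube A (flat-fielded) [hypercube].
#' @param masks Named list of logical patch masks.
#' @param standard_mask Logical mask over the reflectance standard, or a
#'   long spectrum tibble to use directly as the standard spectrum.
#' @param species,specimen,view Label strings attached to every row.
#' @param target_n Target number of samples per patch (default 1000).
#' @param window Sampling window side (default 10).
#' @param nominal Nominal reflectance of the standard (default 1).
#' @param calibrate If `FALSE`, spectra are returned uncalibrated (for cubes
#'   that are already reflectance).
#' @return A wide sample-set tibble: `species`, `specimen`, `view`, `patch`,
#'   `row`, `col`, then one `wl_<nm>` column per band.
#' @export
build_sampleset <- function(cube, masks, standard_mask = NULL,
                            species = "unknown", specimen = "unknown",
                            view = "unknown", target_n = 1000, window = 10,
                            nominal = 1, calibrate = !is.null(standard_mask)) {
  stopifnot(is.list(masks), !is.null(names(masks)))
  d <- dim(cube$data)
  std_spec <- NULL
  std_mask <- NULL
  if (!is.null(standard_mask)) {
    if (is.data.frame(standard_mask)) {
      std_spec <- check_spectrum_tbl(standard_mask, "standard_mask")
    } else {
      std_mask <- check_mask(standard_mask, d[1:2])
      std_spec <- standard_spectrum(cube, std_mask)
    }
  }
  out <- purrr::imap(masks, function(mask, patch) {
    mask <- check_mask(mask, d[1:2])
    locs <- grid_locations(mask, target_n)
    if (!is.null(std_mask)) {
      keep <- vapply(seq_len(nrow(locs)), function(i) {
        rb <- window_bounds(locs$row[i], window, d[1])
        cb <- window_bounds(locs$col[i], window, d[2])
        !any(std_mask[rb[1]:rb[2], cb[1]:cb[2]])
      }, logical(1))
      if (any(!keep)) {
        inform(sprintf(
          "patch '%s': excluded %d location(s) overlapping the standard",
          patch, sum(!keep)), class = "avicube_standard_overlap")
        locs <- locs[keep, , drop = FALSE]
      }
    }
    specs <- vapply(seq_len(nrow(locs)), function(i) {
      extract_sample(cube, c(locs$row[i], locs$col[i]), window)$reflectance
    }, numeric(d[3]))
    m <- t(specs)
    meta <- tibble(species = species, specimen = specimen, view = view,
                   patch = patch, row = locs$row, col = locs$col)
    set_spectra(meta, m, cube$wavelengths)
  })
  res <- dplyr::bind_rows(out)
  if (calibrate && !is.null(std_spec)) {
    res <- to_reflectance(res, std_spec, nominal = nominal)
  }
  res
}
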