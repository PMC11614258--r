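# Visual-system-independent colour space: per-patch PCA of brightness-
# normalised spectra, 2-D UMAP of the PCA scores, Gaussian-kernel density
# fields with highest-density-region contours, and retrieval of the spectra
# nearest each group's density mode.

#' PCA embedding of reflectance spectra
#'
#' Each spectrum first has its own scalar mean reflectance subtracted
#' (brightness removal, leaving spectral shape), then conventional PCA
#' (dataset-mean centred) produces `n_components` scores per spectrum.
#' With `by = "patch"` (the default used for plumage data) an independent
#' PCA is fitted per patch, since different patches need not share
#' principal axes.
#'
#' @param samples Wide sample-set tibble with `wl_<nm>` columns.
#' @param n_components Number of retained components (default 20).
#' @param by Optional metadata column name to fit one PCA per group
#'   (`NULL` = single pooled PCA).
#' @param center One of `"per_spectrum"` (subtract each spectrum's scalar
#'   mean; default) or `"mean_spectrum"` (subtract the dataset mean
#'   spectrum only).
#' @return A `spectral_embedding` object: tibble `scores` (metadata +
#'   `pc1..pcK`), list `explained_variance` per group, and the settings.
#' @export
pca_embed <- function(samples, n_components = 20, by = NULL,
                      center = c("per_spectrum", "mean_spectrum")) {
  center <- match.arg(center)
  m <- spectra_matrix(samples)
  meta <- samples[, !is_wl_col(names(samples)), drop = FALSE]
  groups <- if (is.null(by)) rep("all", nrow(m)) else as.character(meta[[by]])
  n_components <- as.integer(n_components)
  scores <- matrix(NA_real_, nrow(m), n_components)
  expl <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < n_components) {
      abort(sprintf(
        "group '%s' has %d spectra but %d components were requested",
        g, length(idx), n_components), class = "avicube_error_value")
    }
    xg <- m[idx, , drop = FALSE]
    if (center == "per_spectrum") xg <- xg - rowMeans(xg)
    p <- prcomp(xg, center = TRUE, scale. = FALSE, rank. = n_components)
    k <- min(n_components, ncol(p$x))
    scores[idx, seq_len(k)] <- p$x[, seq_len(k)]
    if (k < n_components) scores[idx, (k + 1):n_components] <- 0
    ev <- p$sdev^2 / sum(p$sdev^2)
    expl[[g]] <- ev[seq_len(min(n_components, length(ev)))]
  }
  colnames(scores) <- paste0("pc", seq_len(n_components))
  structure(list(
    scores = dplyr::bind_cols(as_tibble(meta), as_tibble(scores)),
    explained_variance = expl,
    by = by, center = center, n_components = n_components,
    seed = NULL), class = "spectral_embedding")
}

#' @export
print.spectral_embedding <- function(x, ...) {
  cat(sprintf("<spectral_embedding> %d spectra, %d components%s%s\n",
              nrow(x$scores), x$n_components,
              if (!is.null(x$by)) paste0(", grouped by ", x$by) else "",
              if ("x" %in% names(x$scores)) ", with 2-D map" else ""))
  invisible(x)
}

#' Broom-style tidiers for spectral embeddings
#'
#' `tidy()` returns the per-spectrum score table; `glance()` one row of
#' summary statistics.
#'
#' @param x A `spectral_embedding`.
#' @param ... Unused.
#' @method tidy spectral_embedding
#' @export
tidy.spectral_embedding <- function(x, ...) x$scores

#' @rdname tidy.spectral_embedding
#' @method glance spectral_embedding
#' @export
glance.spectral_embedding <- function(x, ...) {
  tibble(
    n = nrow(x$scores),
    n_components = x$n_components,
    n_groups = length(x$explained_variance),
    mean_var_explained = mean(vapply(x$explained_variance, sum, numeric(1))),
    has_map = "x" %in% names(x$scores))
}

#' 2-D manifold (UMAP) embedding of PCA scores
#'
#' Uniform manifold approximation and projection of the PCA coordinates to
#' two dimensions, deterministic for a fixed seed. Degenerate all-identical
#' input collapses to the origin rather than erroring.
#'
#' @param x A `spectral_embedding` (scores are used and `x`, `y` columns
#'   added) or a numeric matrix.
#' @param seed Integer random seed (default 42).
#' @param n_neighbors,min_dist UMAP hyper-parameters (defaults 15, 0.1).
#' @return Same class as `x` with 2-D coordinates attached (matrix input
#'   returns an `n x 2` matrix).
#' @export
manifold_embed <- function(x, seed = 42, n_neighbors = 15, min_dist = 0.1) {
  m <- if (inherits(x, "spectral_embedding")) {
    as.matrix(x$scores[, grepl("^pc[0-9]+$", names(x$scores)), drop = FALSE])
  } else as.matrix(x)
  if (nrow(m) < 10) {
    abort("need at least 10 rows for a manifold embedding",
          class = "avicube_error_value")
  }
  if (all(apply(m, 2, function(v) diff(range(v))) < 1e-15)) {
    coords <- matrix(0, nrow(m), 2)
  } else {
    nn <- min(n_neighbors, nrow(m) - 1)
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    coords <- uwot::umap(m, n_neighbors = nn, min_dist = min_dist,
                         n_threads = 1, n_sgd_threads = 0)
  }
  colnames(coords) <- c("x", "y")
  if (inherits(x, "spectral_embedding")) {
    x$scores$x <- coords[, 1]
    x$scores$y <- coords[, 2]
    x$seed <- seed
    x
  } else coords
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Scott's rule bandwidth per axis; MASS::kde2d's `h` is 4x the Gaussian sd.
scott_bandwidth <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-8) s <- 1e-3   # bandwidth floor for singular data
  s * length(v)^(-1 / 6)
}

#' Kernel-density fields and highest-density-region contours
#'
#' Per-group Gaussian kernel density on one shared 256 x 256 grid spanning
#' the pooled bounding box (padded 10 %), with Scott's-rule bandwidths per
#' group. For each group the contour level `t` is chosen so the region
#' `{density >= t}` holds `mass` of the group's probability (the highest-
#' density region); the mode is the grid argmax.
#'
#' @param coords Tibble/data frame with `x`, `y` columns (e.g. the scores
#'   of a mapped `spectral_embedding`).
#' @param group Name of the grouping column in `coords` (or a vector).
#' @param mass Probability mass enclosed by the contour (default 0.8).
#' @param grid_n Grid resolution per axis (default 256).
#' @param pad Fractional bounding-box padding (default 0.1).
#' @return A `density_field` object: grid axes, per-group density matrices,
#'   HDR levels, and a tibble of modes.
#' @export
density_contours <- function(coords, group, mass = 0.8, grid_n = 256,
                             pad = 0.1) {
  g <- if (length(group) == 1 && is.character(group)) coords[[group]] else group
  g <- as.character(g)
  stopifnot(length(g) == nrow(coords), mass > 0, mass <= 1)
  xr <- range(coords$x); yr <- range(coords$y)
  xr <- xr + c(-1, 1) * pad * max(diff(xr), 1e-6)
  yr <- yr + c(-1, 1) * pad * max(diff(yr), 1e-6)
  fields <- list(); levels <- numeric(); modes <- list(); bw <- list()
  for (gg in unique(g)) {
    idx <- g == gg
    if (sum(idx) < 10) {
      abort(sprintf("group '%s' has fewer than 10 points", gg),
            class = "avicube_error_value")
    }
    hx <- scott_bandwidth(coords$x[idx]); hy <- scott_bandwidth(coords$y[idx])
    if (stats::sd(coords$x[idx]) < 1e-8 || stats::sd(coords$y[idx]) < 1e-8) {
      warn(sprintf("group '%s' is (near-)singular; bandwidth floored", gg))
    }
    kd <- MASS::kde2d(coords$x[idx], coords$y[idx], h = c(4 * hx, 4 * hy),
                      n = grid_n, lims = c(xr, yr))
    cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    z <- kd$z / (sum(kd$z) * cell)     # renormalise on the truncated grid
    dens <- sort(as.vector(z), decreasing = TRUE)
    cum <- cumsum(dens) * cell
    k <- which(cum >= mass)[1]
    levels[[gg]] <- if (mass >= 1 || is.na(k)) 0 else dens[[k]]
    am <- which(z == max(z), arr.ind = TRUE)[1, ]
    modes[[gg]] <- tibble(group = gg, x = kd$x[am[1]], y = kd$y[am[2]],
                          density = max(z))
    fields[[gg]] <- z
    bw[[gg]] <- c(hx, hy)
  }
  structure(list(
    x = seq(xr[1], xr[2], length.out = grid_n),
    y = seq(yr[1], yr[2], length.out = grid_n),
    density = fields, levels = levels, bandwidth = bw,
    modes = dplyr::bind_rows(modes), mass = mass),
    class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %d group(s), %.0f%% HDR, %d x %d grid\n",
              length(x$density), 100 * x$mass, length(x$x), length(x$y)))
  invisible(x)
}

# Fraction of a group's points lying inside its HDR contour.
hdr_coverage <- function(field, coords, group) {
  g <- as.character(coords[[group]])
  out <- numeric()
  for (gg in names(field$density)) {
    idx <- g == gg
    ix <- findInterval(coords$x[idx], field$x, all.inside = TRUE)
    iy <- findInterval(coords$y[idx], field$y, all.inside = TRUE)
    d <- field$density[[gg]][cbind(ix, iy)]
    out[[gg]] <- mean(d >= field$levels[[gg]])
  }
  out
}

#' Spectra nearest each group's density mode
#'
#' For each group, the `k` samples nearest (Euclidean, in the 2-D map) to
#' the group's kernel-density mode, summarised by per-band median and
#' median absolute deviation. These "mode spectra" characterise the most
#' typical colour of the group.
#'
#' @param field A `density_field` from [density_contours()].
#' @param coords Tibble with `x`, `y` and the grouping column, row-aligned
#'   with `samples`.
#' @param samples Wide sample-set tibble (same row order as `coords`).
#' @param group Grouping column name.
#' @param k Number of nearest spectra per group (default 50; capped at the
#'   group size with a warning).
#' @return Long tibble: `group`, `wavelength`, `median`, `mad`, `n`.
#' @export
mode_spectra <- function(field, coords, samples, group, k = 50) {
  stopifnot(nrow(coords) == nrow(samples))
  m <- spectra_matrix(samples)
  wl <- attr(m, "wavelengths")
  g <- as.character(coords[[group]])
  out <- list()
  for (gg in names(field$density)) {
    idx <- which(g == gg)
    kk <- k
    if (kk > length(idx)) {
      warn(sprintf("group '%s': k = %d exceeds group size %d; capped",
                   gg, k, length(idx)))
      kk <- length(idx)
    }
    mode_xy <- field$modes[field$modes$group == gg, c("x", "y")]
    d2 <- (coords$x[idx] - mode_xy$x)^2 + (coords$y[idx] - mode_xy$y)^2
    sel <- idx[order(d2)[seq_len(kk)]]
    sub <- m[sel, , drop = FALSE]
    out[[gg]] <- tibble(
      group = gg, wavelength = wl,
      median = unname(apply(sub, 2, median)),
      mad = unname(apply(sub, 2, mad)),
      n = kk)
  }
  dplyr::bind_rows(out)
}
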