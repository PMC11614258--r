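# Fixtures built in code: tiny cubes, spheres, and a reusable small scene.

tiny_cube <- function(lines = 4, samples = 5, bands = 6, seed = 1,
                      wavelengths = seq(400, 400 + 10 * (bands - 1), by = 10)) {
  set.seed(seed)
  hypercube(array(runif(lines * samples * bands), dim = c(lines, samples, bands)),
            wavelengths)
}

# UV sphere triangle mesh of radius r centred at the origin.
sphere_mesh <- function(n_lon = 192, n_lat = 96, r = 1) {
  th <- seq(0, pi, length.out = n_lat + 1)
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  g <- expand.grid(th = th, ph = ph)
  v <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph),
             r * cos(g$th))
  vid <- function(i, j) ((j - 1) %% n_lon) * (n_lat + 1) + i
  f <- list()
  for (j in 1:n_lon) {
    for (i in 1:n_lat) {
      a <- vid(i, j); b <- vid(i + 1, j)
      cc <- vid(i, j + 1); dd <- vid(i + 1, j + 1)
      f[[length(f) + 1]] <- c(a, b, dd)
      f[[length(f) + 1]] <- c(a, dd, cc)
    }
  }
  trimesh(v, do.call(rbind, f))
}

identity_pose <- function(scale, center_col, center_row) {
  structure(list(rotation = diag(3), scale = scale,
                 translation = c(center_col, -center_row), rmse = 0),
            class = "ortho_pose")
}

# Wide sample-set tibble from a matrix of spectra.
wide_samples <- function(m, wavelengths, patch = "p") {
  meta <- tibble::tibble(species = "syn", specimen = "s1", view = "v",
                         patch = rep_len(patch, nrow(m)),
                         row = seq_len(nrow(m)), col = 1L)
  colnames(m) <- paste0("wl_", format(wavelengths, trim = TRUE,
                                      scientific = FALSE, digits = 12))
  dplyr::bind_cols(meta, tibble::as_tibble(m))
}

# Independent RNL oracle: dS is the weighted least-squares residual of the
# receptor signals around their optimal common (achromatic) offset -- the
# projection formulation, algebraically distinct from the pairwise-term
# transcription used in the package.
rnl_oracle <- function(QA, QB, e) {
  f <- log(QA / QB)
  w <- 1 / e^2
  cbar <- sum(w * f) / sum(w)
  sqrt(sum(((f - cbar) / e)^2))
}
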