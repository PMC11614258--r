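# Synthetic hyperspectral scenes with known ground truth: parametric
# reflectance spectra, a white-standard region, a directional-lighting
# column gradient, additive sensor noise, and (for the 3D workflow) an
# ellipsoid specimen whose iridescent patch shifts its spectral peak with
# surface pitch. Every stage of the pipeline is testable against the
# returned truth bundle, with no external downloads.

#' Parametric reflectance spectrum models
#'
#' Deterministic spectra emulating common plumage reflectance shapes:
#' `sigmoid_step` (carotenoid-like long-pass step), `gaussian_peak`
#' (structural colour peak), `flat` (white/grey), `linear_ramp` (brown
#' ramp).
#'
#' @param kind One of `"sigmoid_step"`, `"gaussian_peak"`, `"flat"`,
#'   `"linear_ramp"`.
#' @param params Named list of parameters: `sigmoid_step` uses `lambda0`,
#'   `steepness` (nm), `lo`, `hi`; `gaussian_peak` uses `lambda0`, `sigma`,
#'   `amplitude`, `baseline`; `flat` uses `level`; `linear_ramp` uses `lo`,
#'   `hi`.
#' @param wavelengths Evaluation grid in nm.
#' @return Tibble `wavelength`, `reflectance`; errors if any value leaves
#'   `[0, 1]`.
#' @export
spectrum_model <- function(kind, params = list(),
                           wavelengths = seq(274, 812, length.out = 294)) {
  kind <- match.arg(kind, c("sigmoid_step", "gaussian_peak", "flat",
                            "linear_ramp"))
  p <- params
  v <- switch(kind,
    sigmoid_step = {
      lo <- p$lo %||% 0.05; hi <- p$hi %||% 0.6
      lam <- p$lambda0 %||% 550; st <- p$steepness %||% 25
      lo + (hi - lo) / (1 + exp(-(wavelengths - lam) / st))
    },
    gaussian_peak = {
      base <- p$baseline %||% 0.1; amp <- p$amplitude %||% 0.5
      lam <- p$lambda0 %||% 530; sig <- p$sigma %||% 40
      base + amp * exp(-((wavelengths - lam)^2) / (2 * sig^2))
    },
    flat = rep(p$level %||% 0.99, length(wavelengths)),
    linear_ramp = {
      lo <- p$lo %||% 0.1; hi <- p$hi %||% 0.6
      lo + (hi - lo) * (wavelengths - min(wavelengths)) /
        diff(range(wavelengths))
    })
  if (any(v < 0) || any(v > 1)) {
    abort("spectrum model parameters produce reflectance outside [0, 1]",
          class = "avicube_error_value")
  }
  tibble(wavelength = wavelengths, reflectance = v)
}

ellipse_mask <- function(dims, center, radii) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  c <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

rect_mask <- function(dims, center, half) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  c <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  abs(r - center[1]) <= half[1] & abs(c - center[2]) <= half[2]
}

#' Synthetic scene specification
#'
#' The default scene mimics a museum-specimen acquisition: a 120 x 160
#' image on the instrument-like 294-band 274-812 nm grid (~1.83 nm
#' spacing, exercising the same interpolation arithmetic as real cubes), a
#' white-standard rectangle (nominal 0.99), four body patches with
#' distinct spectrum models, a directional-lighting column gradient, and
#' additive Gaussian sensor noise.
#'
#' @param dims `c(lines, samples)` (default `c(120, 160)`).
#' @param wavelengths Band-center grid (default 294 bands, 274-812 nm).
#' @param patches Named list; each element is a list with `shape`
#'   (`"ellipse"`/`"rect"`), `center`, `radii` or `half`, and `spectrum`
#'   (a list with `kind` and `params`). `NULL` uses the 4-patch default.
#' @param standard List with `center`, `half`, `nominal` for the white
#'   standard (default nominal 0.99).
#' @param gradient Peak-to-peak fractional amplitude of the linear column
#'   illumination gradient (default 0.2).
#' @param noise_sd Additive Gaussian radiance noise sd (default 0.01).
#' @param seed Integer seed fixing all randomness (default 1).
#' @return A `scene_spec` list; patches and standard must not overlap.
#' @export
scene_spec <- function(dims = c(120, 160),
                       wavelengths = seq(274, 812, length.out = 294),
                       patches = NULL, standard = NULL,
                       gradient = 0.2, noise_sd = 0.01, seed = 1) {
  stopifnot(length(dims) == 2, all(dims >= 20), noise_sd >= 0)
  if (is.null(patches)) {
    patches <- list(
      breast = list(shape = "ellipse", center = c(0.30, 0.22), radii = c(0.18, 0.12),
                    spectrum = list(kind = "sigmoid_step",
                                    params = list(lambda0 = 560, steepness = 28,
                                                  lo = 0.05, hi = 0.65))),
      back = list(shape = "ellipse", center = c(0.30, 0.60), radii = c(0.18, 0.12),
                  spectrum = list(kind = "gaussian_peak",
                                  params = list(lambda0 = 530, sigma = 45,
                                                amplitude = 0.5, baseline = 0.08))),
      belly_vent = list(shape = "ellipse", center = c(0.75, 0.22), radii = c(0.18, 0.12),
                        spectrum = list(kind = "flat",
                                        params = list(level = 0.85))),
      shoulder = list(shape = "ellipse", center = c(0.75, 0.60), radii = c(0.18, 0.12),
                      spectrum = list(kind = "linear_ramp",
                                      params = list(lo = 0.12, hi = 0.55))))
  }
  if (is.null(standard)) {
    standard <- list(center = c(0.5, 0.90), half = c(0.35, 0.06),
                     nominal = 0.99)
  }
  masks <- list()
  for (nm in names(patches)) {
    p <- patches[[nm]]
    ctr <- p$center * dims
    masks[[nm]] <- if (identical(p$shape, "rect")) {
      rect_mask(dims, ctr, p$half * dims)
    } else {
      ellipse_mask(dims, ctr, p$radii * dims)
    }
  }
  std_mask <- rect_mask(dims, standard$center * dims, standard$half * dims)
  overlap <- Reduce(`+`, masks) + std_mask
  if (any(overlap > 1)) {
    abort("patches and standard regions overlap", class = "avicube_error_value")
  }
  structure(list(dims = dims, wavelengths = wavelengths, patches = patches,
                 standard = standard, masks = masks, std_mask = std_mask,
                 gradient = gradient, noise_sd = noise_sd, seed = seed),
            class = "scene_spec")
}

#' Simulate a hyperspectral cube with ground truth
#'
#' Radiance is `illuminant x gradient(column) x reflectance + noise`. The
#' matching bright cube (uniform white target under the same illumination
#' field) is returned for flat-fielding, along with the patch masks, the
#' true spectra, and the gradient, so calibration and sampling can be
#' validated exactly.
#'
#' @param spec A [scene_spec()].
#' @param bright_lines Number of lines in the bright cube (default 12).
#' @return List: `cube`, `bright` (both [hypercube]), `masks` (named list,
#'   incl. `standard`), `truth` (list: `spectra` named list of long
#'   tibbles, `gradient`, `nominal`, `background`).
#' @export
simulate_cube <- function(spec, bright_lines = 12) {
  stopifnot(inherits(spec, "scene_spec"))
  d <- spec$dims; wl <- spec$wavelengths; nb <- length(wl)
  grad <- 1 + spec$gradient * ((seq_len(d[2]) - 1) / (d[2] - 1) - 0.5)
  refl <- array(0.02, dim = c(d, nb))        # dark background
  truth <- list()
  for (nm in names(spec$patches)) {
    sm <- spectrum_model(spec$patches[[nm]]$spectrum$kind,
                         spec$patches[[nm]]$spectrum$params, wl)
    truth[[nm]] <- sm
    idx <- which(spec$masks[[nm]])
    for (b in seq_len(nb)) {
      plane <- refl[, , b]
      plane[idx] <- sm$reflectance[b]
      refl[, , b] <- plane
    }
  }
  std <- spectrum_model("flat", list(level = spec$standard$nominal), wl)
  idx <- which(spec$std_mask)
  for (b in seq_len(nb)) {
    plane <- refl[, , b]
    plane[idx] <- std$reflectance[b]
    refl[, , b] <- plane
  }
  gcube <- array(rep(grad, each = d[1]), dim = c(d, nb))
  set.seed(spec$seed)
  noise <- if (spec$noise_sd > 0) {
    array(rnorm(prod(d) * nb, sd = spec$noise_sd), dim = c(d, nb))
  } else 0
  rad <- pmax(refl * gcube + noise, 0)
  cube <- hypercube(rad, wl, meta = list(description = "synthetic radiance",
                                         seed = spec$seed))
  bright <- hypercube(
    array(rep(grad, each = bright_lines), dim = c(bright_lines, d[2], nb)),
    wl, meta = list(description = "synthetic bright image"))
  masks <- c(spec$masks, list(standard = spec$std_mask))
  list(cube = cube, bright = bright, masks = masks,
       truth = list(spectra = truth, gradient = grad,
                    nominal = spec$standard$nominal, background = 0.02))
}

#' Simulate an ellipsoid specimen with an angle-dependent (iridescent) patch
#'
#' An ellipsoid viewed orthographically along -Z fills the image center.
#' Within the visible ellipse every pixel's analytic surface normal gives
#' its pitch; the iridescent patch reflects a Gaussian peak whose center
#' shifts as `lambda0 - k * pitch` (nm per radian). The matching triangle
#' mesh (UV-parameterised), >= 4 exact landmark correspondences, the
#' analytic pitch map, and the truth parameters are returned.
#'
#' @param dims Image size `c(lines, samples)` (default `c(96, 96)`).
#' @param wavelengths Band grid (default 294 bands 274-812 nm).
#' @param k Iridescence coefficient, nm of peak shift per radian of pitch
#'   (default 100).
#' @param lambda0 Peak wavelength at zero pitch (default 550).
#' @param sigma Peak width (default 35 nm).
#' @param noise_sd Additive noise sd (default 0).
#' @param mesh_res `c(n_lon, n_lat)` mesh resolution (default `c(96, 48)`).
#' @param seed Integer seed (default 1).
#' @return List: `cube` (reflectance [hypercube]), `mesh`, `landmarks`
#'   (tibble row/col/X/Y/Z), `pitch` (analytic per-pixel map), `mask`
#'   (specimen pixels), `truth` (list `k`, `lambda0`, `sigma`, `scale`).
#' @export
simulate_scene3d <- function(dims = c(96, 96),
                             wavelengths = seq(274, 812, length.out = 294),
                             k = 100, lambda0 = 550, sigma = 35,
                             noise_sd = 0, mesh_res = c(96, 48), seed = 1) {
  nr <- dims[1]; nc <- dims[2]; nb <- length(wavelengths)
  # ellipsoid semi-axes in mesh units; scale chosen to fill ~80% of image
  ax <- c(1.0, 0.75, 0.6)
  s <- 0.4 * min(nc / ax[1], nr / ax[2])
  ctr <- c((nc + 1) / 2, (nr + 1) / 2)      # (col, row) center
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rows <- matrix(seq_len(nr), nr, nc)
  X <- (cols - ctr[1]) / s                  # camera x (right)
  Y <- -(rows - ctr[2]) / s                 # camera y (up)
  inside <- (X / ax[1])^2 + (Y / ax[2])^2 < 1
  Zs <- sqrt(pmax(1 - (X / ax[1])^2 - (Y / ax[2])^2, 0)) * ax[3]
  # outward normal of x^2/a^2 + y^2/b^2 + z^2/c^2 = 1
  nx <- X / ax[1]^2; ny <- Y / ax[2]^2; nz <- Zs / ax[3]^2
  pitch <- matrix(NA_real_, nr, nc)
  pitch[inside] <- atan2(ny[inside], nz[inside])
  set.seed(seed)
  refl <- array(0.02, dim = c(nr, nc, nb))
  pk <- lambda0 - k * pitch
  for (b in seq_len(nb)) {
    plane <- refl[, , b]
    plane[inside] <- 0.08 +
      0.5 * exp(-((wavelengths[b] - pk[inside])^2) / (2 * sigma^2))
    refl[, , b] <- plane
  }
  if (noise_sd > 0) {
    refl <- pmax(refl + array(rnorm(length(refl), sd = noise_sd),
                              dim = dim(refl)), 0)
  }
  cube <- hypercube(refl, wavelengths,
                    meta = list(reflectance = TRUE, seed = seed))
  # UV ellipsoid mesh in mesh units (camera frame = mesh frame: identity pose)
  n_lon <- mesh_res[1]; n_lat <- mesh_res[2]
  th <- seq(0, pi, length.out = n_lat + 1)            # colatitude
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  grid <- expand.grid(th = th, ph = ph)
  verts <- cbind(ax[1] * sin(grid$th) * cos(grid$ph),
                 ax[2] * sin(grid$th) * sin(grid$ph),
                 ax[3] * cos(grid$th))
  vid <- function(i, j) ((j - 1) %% n_lon) * (n_lat + 1) + i
  faces <- list()
  for (j in seq_len(n_lon)) {
    for (i in seq_len(n_lat)) {
      a <- vid(i, j); b <- vid(i + 1, j)
      cc <- vid(i, j + 1); dd <- vid(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, b, dd)
      faces[[length(faces) + 1]] <- c(a, dd, cc)
    }
  }
  mesh <- trimesh(verts, do.call(rbind, faces))
  # landmarks: visible (z > 0) points at exact projections
  lm_pts <- rbind(
    c(0.5, 0.2, 1), c(-0.4, 0.3, 1), c(0.2, -0.5, 1), c(-0.5, -0.3, 1),
    c(0.0, 0.0, 1))
  lm_xyz <- t(apply(lm_pts, 1, function(p) {
    v <- c(p[1] * ax[1], p[2] * ax[2], 0)
    z <- sqrt(max(1 - p[1]^2 - p[2]^2, 0)) * ax[3]
    c(v[1], v[2], z)
  }))
  landmarks <- tibble(
    name = paste0("lm", seq_len(nrow(lm_xyz))),
    row = ctr[2] - s * lm_xyz[, 2],
    col = ctr[1] + s * lm_xyz[, 1],
    X = lm_xyz[, 1], Y = lm_xyz[, 2], Z = lm_xyz[, 3])
  list(cube = cube, mesh = mesh, landmarks = landmarks, pitch = pitch,
       mask = inside, truth = list(k = k, lambda0 = lambda0, sigma = sigma,
                                   scale = s, axes = ax))
}
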