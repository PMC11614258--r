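# Avian receptor systems: pigment-template sensitivity curves, quantum
# catches under an ideal (flat) illuminant with von-Kries normalisation to
# an ideal white background, and tetrahedral colour-space coordinates.

#' Visual pigment template sensitivity (A1 nomogram)
#'
#' Govardovskii et al. (2000) A1 rhodopsin template: alpha band plus beta
#' band, peak-normalised to 1 at `lambda_max`.
#'
#' @param lambda_max Peak wavelength (nm), within 300-700.
#' @param wavelengths Evaluation grid (default 300:700).
#' @return Numeric sensitivity vector, peak-normalised.
#' @export
pigment_template <- function(lambda_max, wavelengths = 300:700) {
  if (lambda_max < 300 || lambda_max > 700) {
    abort("`lambda_max` must lie within 300-700 nm",
          class = "avicube_error_value")
  }
  x <- lambda_max / wavelengths
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wavelengths - lmb) / bb)^2)
  s <- alpha + beta
  s / max(s)
}

#' Receptor system of an average violet-sensitive (VS) bird
#'
#' Builds the four single-cone sensitivities (VS, SWS, MWS, LWS) plus an
#' optional double cone on the 300-700 nm 1 nm grid. Curves are generated
#' from the A1 visual-pigment nomogram at the given peak wavelengths; the
#' defaults (416, 478, 542, 607 nm) are typical average-VS values from the
#' comparative avian vision literature and are fully configurable — they
#' are nomogram approximations, not a copy of any published curve table.
#' Alternatively `source` may name a CSV (`wavelength_nm, vs, sws, mws,
#' lws[, dbl]`) of measured curves.
#'
#' Cone abundances default to `(1, 1, 1, 2)` (VS, SWS, MWS, LWS), the
#' ratios reported for the Rock dove, and the chromatic Weber fraction to
#' 0.1, anchored to the most abundant cone.
#'
#' @param lambda_max Named numeric, peaks for `vs`, `sws`, `mws`, `lws`.
#' @param abundances Relative cone abundances, same order.
#' @param weber Chromatic Weber fraction (most abundant cone).
#' @param weber_achro Achromatic (double-cone) Weber fraction.
#' @param double_cone `"lws_template"` (nomogram at the LWS peak; default),
#'   `"none"`, or a numeric peak wavelength.
#' @param source Optional CSV path overriding the template curves.
#' @return A `receptor_system`: tibble `sensitivities` plus noise
#'   parameters.
#' @export
vs_bird_receptors <- function(lambda_max = c(vs = 416, sws = 478,
                                             mws = 542, lws = 607),
                              abundances = c(vs = 1, sws = 1, mws = 1, lws = 2),
                              weber = 0.1, weber_achro = 0.1,
                              double_cone = "lws_template", source = NULL) {
  wl <- 300:700
  cones <- c("vs", "sws", "mws", "lws")
  if (!is.null(source)) {
    tab <- as_tibble(read.csv(source))
    names(tab)[1] <- "wavelength"
    missing_cols <- setdiff(cones, names(tab))
    if (length(missing_cols)) {
      abort(paste("receptor CSV lacks columns:",
                  paste(missing_cols, collapse = ", ")),
            class = "avicube_error_format")
    }
    sens <- tibble(wavelength = wl)
    for (cn in intersect(c(cones, "dbl"), names(tab))) {
      sens[[cn]] <- approx(tab$wavelength, tab[[cn]], xout = wl, rule = 2)$y
      sens[[cn]] <- sens[[cn]] / max(sens[[cn]])
    }
    lambda_max <- vapply(cones, function(cn) wl[which.max(sens[[cn]])],
                         numeric(1))
  } else {
    stopifnot(all(cones %in% names(lambda_max)))
    if (is.unsorted(lambda_max[cones], strictly = TRUE)) {
      abort("peaks must be ordered vs < sws < mws < lws",
            class = "avicube_error_value")
    }
    sens <- tibble(wavelength = wl)
    for (cn in cones) sens[[cn]] <- pigment_template(lambda_max[[cn]], wl)
    if (identical(double_cone, "lws_template")) {
      sens$dbl <- pigment_template(lambda_max[["lws"]], wl)
    } else if (is.numeric(double_cone)) {
      sens$dbl <- pigment_template(double_cone, wl)
    }
  }
  stopifnot(all(abundances > 0), weber > 0, weber_achro > 0)
  structure(list(
    sensitivities = sens,
    abundances = setNames(as.numeric(abundances[cones]), cones),
    weber = weber, weber_achro = weber_achro,
    lambda_max = lambda_max), class = "receptor_system")
}

#' @export
print.receptor_system <- function(x, ...) {
  cat(sprintf(
    "<receptor_system> peaks %s nm; abundances (%s); Weber %.2f/%.2f%s\n",
    paste(round(unlist(x$lambda_max)), collapse = "/"),
    paste(x$abundances, collapse = ","), x$weber, x$weber_achro,
    if ("dbl" %in% names(x$sensitivities)) " (+double cone)" else ""))
  invisible(x)
}

# Receptor noise e_i = w * sqrt(n_max / n_i): Weber fraction anchored to the
# most abundant cone.
receptor_noise <- function(rec) {
  n <- rec$abundances
  rec$weber * sqrt(max(n) / n)
}

#' Quantum catches and tetrahedral coordinates of reflectance spectra
#'
#' Under an ideal (flat) illuminant and von-Kries adaptation to an ideal
#' white background, the catch of receptor i reduces to
#' `Q_i = sum(R * S_i) / sum(S_i)` so that a perfect white gives `Q_i = 1`
#' for every cone. Relative catches `q_i = Q_i / sum(Q)` and the
#' tetrahedral `(x, y, z)` coordinates are appended.
#'
#' @param x Wide sample-set tibble or long spectrum tibble on the
#'   300-700 nm 1 nm grid.
#' @param rec A `receptor_system`.
#' @return Tibble: input metadata plus `Q_vs..Q_lws` (and `Q_dbl` when the
#'   system has a double cone), `q_vs..q_lws`, and `x`, `y`, `z`.
#' @export
quantum_catch <- function(x, rec) {
  stopifnot(inherits(rec, "receptor_system"))
  if (any(is_wl_col(names(x)))) {
    m <- spectra_matrix(x)
    wl <- attr(m, "wavelengths")
    meta <- x[, !is_wl_col(names(x)), drop = FALSE]
  } else {
    check_spectrum_tbl(x)
    m <- matrix(x$reflectance, nrow = 1)
    wl <- x$wavelength
    meta <- tibble(.rows = 1)
  }
  swl <- rec$sensitivities$wavelength
  if (length(wl) != length(swl) || max(abs(wl - swl)) > 1e-9) {
    abort("spectra must be on the receptor grid (300-700 nm at 1 nm); run prep_spectra first",
          class = "avicube_error_coverage")
  }
  cones <- c("vs", "sws", "mws", "lws")
  has_dbl <- "dbl" %in% names(rec$sensitivities)
  chan <- c(cones, if (has_dbl) "dbl")
  S <- as.matrix(rec$sensitivities[, chan, drop = FALSE])
  Q <- m %*% sweep(S, 2, colSums(S), `/`)
  colnames(Q) <- paste0("Q_", chan)
  q <- Q[, paste0("Q_", cones), drop = FALSE] /
    rowSums(Q[, paste0("Q_", cones), drop = FALSE])
  colnames(q) <- paste0("q_", cones)
  xyz <- tetra_coords(q)
  dplyr::bind_cols(as_tibble(meta), as_tibble(Q), as_tibble(q), xyz)
}

#' Tetrahedral colour-space coordinates from relative catches
#'
#' Maps relative catches `(u, s, m, l)` (= VS, SWS, MWS, LWS; summing to 1)
#' into the standard avian tetrahedron: the achromatic point is the origin
#' and each pure-receptor vertex lies at distance 0.75:
#' `x = ((1 - 2s - m - u)/2) * sqrt(3/2)`,
#' `y = (-1 + 3m + u) / (2 * sqrt(2))`,
#' `z = u - 1/4`.
#'
#' @param q Numeric length-4 vector, or matrix with 4 columns, in VS, SWS,
#'   MWS, LWS order (named `q_*` columns are also accepted).
#' @return Tibble with columns `x`, `y`, `z`.
#' @export
tetra_coords <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  q <- as.matrix(q)
  if (ncol(q) != 4) {
    abort("`q` needs 4 relative catches (vs, sws, mws, lws)",
          class = "avicube_error_value")
  }
  if (any(q < -1e-9) || any(abs(rowSums(q) - 1) > 1e-8)) {
    abort("relative catches must be non-negative and sum to 1",
          class = "avicube_error_value")
  }
  u <- unname(q[, 1]); s <- unname(q[, 2]); m <- unname(q[, 3])
  tibble(
    x = ((1 - 2 * s - m - u) / 2) * sqrt(3 / 2),
    y = (-1 + 3 * m + u) / (2 * sqrt(2)),
    z = u - 0.25)
}
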