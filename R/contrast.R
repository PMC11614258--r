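# Receptor-noise-limited (RNL) discrimination modelling: chromatic contrast
# dS from the tetrachromatic Vorobyev-Osorio formula, luminance contrast dL
# from the double-cone channel, and the >= threshold discriminability call.

catch_vector <- function(Q, arg = "Q") {
  cones <- c("vs", "sws", "mws", "lws")
  if (is.data.frame(Q)) {
    cols <- paste0("Q_", cones)
    if (!all(cols %in% names(Q))) {
      abort(sprintf("`%s` must carry columns %s", arg,
                    paste(cols, collapse = ", ")),
            class = "avicube_error_format")
    }
    Q <- as.numeric(Q[1, cols])
  }
  Q <- as.numeric(Q)
  if (length(Q) != 4) {
    abort(sprintf("`%s` must hold 4 cone catches", arg),
          class = "avicube_error_value")
  }
  if (any(!is.finite(Q)) || any(Q <= 0)) {
    abort(sprintf(
      "`%s` must be positive and finite (apply a catch floor, e.g. 1e-9, to black pixels)",
      arg), class = "avicube_error_value")
  }
  Q
}

#' Chromatic contrast under the receptor-noise-limited model
#'
#' Tetrachromatic Vorobyev-Osorio contrast between two stimuli, in
#' just-noticeable-difference (JND)-like units. Signals are
#' `f_i = ln(Q_i^A / Q_i^B)`; receptor noise `e_i = w * sqrt(n_max / n_i)`
#' anchors the Weber fraction `w` to the most abundant cone. The contrast
#' is brightness-invariant: scaling either spectrum leaves dS unchanged.
#'
#' @param QA,QB Length-4 positive cone-catch vectors (VS, SWS, MWS, LWS),
#'   or one-row catch tibbles from [quantum_catch()].
#' @param rec A `receptor_system`.
#' @return dS (non-negative scalar).
#' @export
rnl_chromatic <- function(QA, QB, rec) {
  stopifnot(inherits(rec, "receptor_system"))
  qa <- catch_vector(QA, "QA"); qb <- catch_vector(QB, "QB")
  f <- log(qa / qb)
  e <- receptor_noise(rec)
  e1 <- e[1]; e2 <- e[2]; e3 <- e[3]; e4 <- e[4]
  num <-
    (e1 * e2)^2 * (f[4] - f[3])^2 +
    (e1 * e3)^2 * (f[4] - f[2])^2 +
    (e1 * e4)^2 * (f[3] - f[2])^2 +
    (e2 * e3)^2 * (f[4] - f[1])^2 +
    (e2 * e4)^2 * (f[3] - f[1])^2 +
    (e3 * e4)^2 * (f[2] - f[1])^2
  den <- (e1 * e2 * e3)^2 + (e1 * e2 * e4)^2 +
    (e1 * e3 * e4)^2 + (e2 * e3 * e4)^2
  unname(sqrt(num / den))
}

#' Luminance contrast under the receptor-noise-limited model
#'
#' `dL = |ln(QA_D / QB_D)| / w_D` where the achromatic channel is the
#' double cone (or its configured proxy).
#'
#' @param QA_D,QB_D Positive achromatic (double-cone) catches.
#' @param rec A `receptor_system` (its `weber_achro` is used).
#' @return dL (non-negative scalar).
#' @export
rnl_luminance <- function(QA_D, QB_D, rec) {
  stopifnot(inherits(rec, "receptor_system"))
  if (is.data.frame(QA_D)) QA_D <- QA_D$Q_dbl[1]
  if (is.data.frame(QB_D)) QB_D <- QB_D$Q_dbl[1]
  if (!is.finite(QA_D) || !is.finite(QB_D) || QA_D <= 0 || QB_D <= 0) {
    abort("achromatic catches must be positive", class = "avicube_error_value")
  }
  abs(log(QA_D / QB_D)) / rec$weber_achro
}

#' Discriminability call at a contrast threshold
#'
#' Two colours are deemed discriminable when the contrast is at or above
#' the threshold (inclusive); 3 JND is a conservative default for museum-
#' specimen comparisons under idealised viewing assumptions.
#'
#' @param contrast Non-negative contrast value(s).
#' @param threshold Threshold (default 3).
#' @return Logical.
#' @export
discriminable <- function(contrast, threshold = 3) {
  stopifnot(all(contrast >= 0))
  contrast >= threshold
}

#' Pairwise patch contrasts from a prepared sample set
#'
#' Follows the per-patch median simplification: within each patch, the
#' median spectrum of every specimen is computed, quantum catches taken,
#' and all specimen pairs compared by dS and dL.
#'
#' @param samples Prepared wide sample-set tibble (300-700 nm grid).
#' @param rec A `receptor_system` with a double cone.
#' @param threshold Discriminability threshold (default 3).
#' @param floor Catch floor applied before logs (default 1e-9); floored
#'   catches are reported.
#' @return Tibble: `patch`, `specimen_a`, `specimen_b`, `dS`, `dL`,
#'   `discriminable_dS`, `discriminable_dL`.
#' @export
patch_contrasts <- function(samples, rec, threshold = 3, floor = 1e-9) {
  m <- spectra_matrix(samples)
  wl <- attr(m, "wavelengths")
  med <- samples %>%
    dplyr::group_by(.data$specimen, .data$patch) %>%
    dplyr::summarise(dplyr::across(dplyr::starts_with("wl_"), median),
                     .groups = "drop")
  catches <- quantum_catch(med, rec)
  n_floored <- sum(catches[grepl("^Q_", names(catches))] < floor)
  if (n_floored > 0) {
    inform(sprintf("%d catch value(s) below %g floored", n_floored, floor),
           class = "avicube_catch_floor")
  }
  out <- list()
  for (p in unique(catches$patch)) {
    sub <- catches[catches$patch == p, ]
    if (nrow(sub) < 2) next
    prs <- utils::combn(nrow(sub), 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      QA <- pmax(as.numeric(sub[a, paste0("Q_", c("vs", "sws", "mws", "lws"))]),
                 floor)
      QB <- pmax(as.numeric(sub[b, paste0("Q_", c("vs", "sws", "mws", "lws"))]),
                 floor)
      dS <- rnl_chromatic(QA, QB, rec)
      dL <- if ("Q_dbl" %in% names(sub)) {
        rnl_luminance(max(sub$Q_dbl[a], floor), max(sub$Q_dbl[b], floor), rec)
      } else NA_real_
      out[[length(out) + 1]] <- tibble(
        patch = p, specimen_a = sub$specimen[a], specimen_b = sub$specimen[b],
        dS = dS, dL = dL,
        discriminable_dS = discriminable(dS, threshold),
        discriminable_dL = if (is.na(dL)) NA else discriminable(dL, threshold))
    }
  }
  dplyr::bind_rows(out)
}

#' Per-pixel cone-catch image from a calibrated cube
#'
#' Applies the visual model to every pixel: the cube's native bands are
#' linearly interpolated to the 1 nm grid, extended down to 300 nm, and
#' integrated against each receptor sensitivity, yielding a 4-channel
#' (5 with double cone) stimulation image suitable for pattern-analysis
#' toolchains.
#'
#' @param cube A calibrated (reflectance) [hypercube] covering 325-700 nm;
#'   refuses radiance cubes unless `force = TRUE`.
#' @param rec A `receptor_system`.
#' @param extend `"constant"` (default; extend the 325 nm value down to
#'   300 nm) or `"prep"` (full smoothing + monotone-cubic extrapolation per
#'   pixel — slower, for small cubes).
#' @param force Process even if the cube is not flagged calibrated.
#' @return `lines x samples x channels` array; channel names in
#'   `dimnames`.
#' @export
cone_catch_image <- function(cube, rec, extend = c("constant", "prep"),
                             force = FALSE) {
  extend <- match.arg(extend)
  calibrated <- isTRUE(cube$meta$flat_fielded) ||
    isTRUE(cube$meta$reflectance) || isTRUE(cube$meta$calibrated)
  if (!calibrated && !force) {
    warn("cube is not flagged as calibrated reflectance")
    abort("refusing to model an uncalibrated cube (use force = TRUE)",
          class = "avicube_error_value")
  }
  d <- dim(cube$data)
  m <- matrix(cube$data, nrow = d[1] * d[2])   # pixels x bands
  wl <- cube$wavelengths
  grid <- 325:700
  if (min(wl) > 325 || max(wl) < 700) {
    abort("cube must cover 325-700 nm", class = "avicube_error_coverage")
  }
  # linear interpolation is a linear map: build it once as a sparse-ish
  # weight assembly via approx on the band index
  idx <- approx(wl, seq_along(wl), xout = grid)$y
  lo <- floor(idx); hi <- pmin(lo + 1, length(wl)); wgt <- idx - lo
  R <- m[, lo, drop = FALSE] * (1 - rep(wgt, each = nrow(m))) +
    m[, hi, drop = FALSE] * rep(wgt, each = nrow(m))
  if (extend == "constant") {
    Rfull <- cbind(matrix(R[, 1], nrow(R), 25), R)
  } else {
    sm <- t(apply(R, 1, function(v) signal::sgolayfilt(v, p = 2, n = 45)))
    ext <- t(apply(sm, 1, function(v)
      extrap_one(grid, v, 300:324, c(325, 700))))
    Rfull <- cbind(ext, sm)
    R <- sm
  }
  cones <- c("vs", "sws", "mws", "lws")
  chan <- c(cones, if ("dbl" %in% names(rec$sensitivities)) "dbl")
  S <- as.matrix(rec$sensitivities[, chan, drop = FALSE])
  Q <- Rfull %*% sweep(S, 2, colSums(S), `/`)
  out <- array(Q, dim = c(d[1], d[2], length(chan)),
               dimnames = list(NULL, NULL, chan))
  out
}

#' Write a cone-catch image as a multichannel 32-bit float TIFF
#'
#' One TIFF page per receptor channel, 32-bit float. The channel order
#' (VS, SWS, MWS, LWS, then the double cone when present) is also written
#' to a `<path>.channels.txt` sidecar, one name per line.
#'
#' @param img Array from [cone_catch_image()].
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_cone_tiff <- function(img, path) {
  chan <- dimnames(img)[[3]] %||% paste0("ch", seq_len(dim(img)[3]))
  pages <- lapply(seq_along(chan), function(k) img[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(chan, paste0(path, ".channels.txt"))
  invisible(path)
}
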