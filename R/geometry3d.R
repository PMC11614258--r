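# Landmark registration of a hyperspectral image to a triangle mesh under a
# scaled-orthographic camera, depth-buffered rasterization of per-pixel
# surface-normal roll/pitch, and angle-binned median +/- MAD spectra.
#
# Camera convention: the camera looks along -Z of its own frame; camera +x
# maps to increasing image column, camera +y points up (decreasing image
# row). Angles: roll = atan2(-n_x, n_z) so roll > 0 means the surface faces
# left of the camera; pitch = atan2(n_y, n_z) so pitch > 0 means it faces
# up. Both lie in [-pi, pi]; background pixels are invalid (NA), never 0.

#' Read / write a triangle mesh in Wavefront OBJ format
#'
#' Minimal OBJ support: `v` vertex lines and `f` face lines (any of the
#' `v`, `v/vt`, `v//vn`, `v/vt/vn` index forms; polygons are fan-
#' triangulated). Negative indices are resolved relative to the current
#' vertex count.
#'
#' @param path OBJ file path.
#' @return A `trimesh`: list with `vertices` (n x 3 matrix) and `faces`
#'   (m x 3 integer matrix, 1-based).
#' @export
read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl) || !length(fl)) {
    abort(sprintf("'%s' contains no triangles", path),
          class = "avicube_error_format")
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- list()
  for (f in strsplit(trimws(sub("^f", "", fl)), "\\s+")) {
    idx <- vapply(f, function(tok) as.integer(strsplit(tok, "/")[[1]][1]),
                  integer(1))
    idx[idx < 0] <- nrow(verts) + 1L + idx[idx < 0]
    for (k in seq_len(length(idx) - 2)) {
      faces[[length(faces) + 1]] <- c(idx[1], idx[k + 1], idx[k + 2])
    }
  }
  trimesh(verts, do.call(rbind, faces))
}

#' @rdname read_obj
#' @param mesh A `trimesh` to write.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Triangle mesh constructor
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3, all(faces >= 1), all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Estimate a scaled-orthographic camera pose from landmarks
#'
#' Museum imaging keeps the imager at a fixed height, so scale is constant
#' and a scaled-orthographic (weak-perspective) model applies. Given >= 3
#' non-collinear image (row, col) to mesh (X, Y, Z) correspondences, the
#' least-squares 2 x 3 projection of the centred 3D points onto the centred
#' image points is computed and factored (SVD orthogonalisation) into a
#' rotation, a single scale, and a translation; the reprojection RMSE is
#' reported. At least 4 non-coplanar landmarks pin the full 3D rotation;
#' coplanar sets leave the out-of-plane component ambiguous.
#'
#' @param landmarks Data frame with columns `row`, `col` (1-based image
#'   pixels) and `X`, `Y`, `Z` (mesh coordinates).
#' @return An `ortho_pose`: `rotation` (3 x 3, mesh -> camera frame),
#'   `scale` (pixels per mesh unit), `translation` (length-2: col, row
#'   offsets), and `rmse` (pixels).
#' @export
estimate_pose <- function(landmarks) {
  need <- c("row", "col", "X", "Y", "Z")
  if (!all(need %in% names(landmarks))) {
    abort("landmarks need columns row, col, X, Y, Z",
          class = "avicube_error_format")
  }
  if (nrow(landmarks) < 3) {
    abort("need at least 3 landmark pairs", class = "avicube_error_value")
  }
  P <- as.matrix(landmarks[, c("X", "Y", "Z")])
  # image coords in camera-aligned axes: u = col (right), v = -row (up)
  U <- cbind(u = landmarks$col, v = -landmarks$row)
  p0 <- colMeans(P); u0 <- colMeans(U)
  Pc <- sweep(P, 2, p0); Uc <- sweep(U, 2, u0)
  sv <- svd(Pc)
  if (sum(sv$d > max(sv$d) * 1e-9) < 2) {
    abort("landmarks are collinear: pose is degenerate",
          class = "avicube_error_degenerate")
  }
  # least-squares M (2 x 3) with Uc' = M Pc'
  M <- t(qr.solve(Pc, Uc))
  dec <- svd(M)
  s <- mean(dec$d)
  R12 <- dec$u %*% t(dec$v[, 1:2, drop = FALSE])  # 2 x 3, orthonormal rows
  r3 <- c(R12[1, 2] * R12[2, 3] - R12[1, 3] * R12[2, 2],
          R12[1, 3] * R12[2, 1] - R12[1, 1] * R12[2, 3],
          R12[1, 1] * R12[2, 2] - R12[1, 2] * R12[2, 1])
  R <- unname(rbind(R12, r3))
  t_uv <- unname(u0 - s * as.numeric(R12 %*% p0))
  proj <- sweep(s * Pc %*% t(R12), 2, u0, `+`)
  rmse <- sqrt(mean((proj - U)^2))
  structure(list(rotation = R, scale = s, translation = t_uv, rmse = rmse),
            class = "ortho_pose")
}

#' @export
print.ortho_pose <- function(x, ...) {
  cat(sprintf("<ortho_pose> scale %.4g px/unit, reprojection RMSE %.3g px\n",
              x$scale, x$rmse))
  invisible(x)
}

# Project mesh vertices with a pose: returns camera-frame coords plus image
# (row, col) positions. Camera looks along -Z, so larger camera-z is nearer.
project_mesh <- function(mesh, pose) {
  cam <- mesh$vertices %*% t(pose$rotation)
  u <- pose$scale * cam[, 1] + pose$translation[1]
  v <- pose$scale * cam[, 2] + pose$translation[2]
  list(cam = cam, col = u, row = -v)
}

#' Render a per-pixel surface-normal map
#'
#' Depth-buffered orthographic rasterization of the posed mesh at the
#' hyperspectral image's resolution: each pixel receives the roll and pitch
#' of the frontmost triangle covering it (`normals = "face"`), or of the
#' barycentric-interpolated vertex normals (`"vertex"`, smoother on curved
#' surfaces). Background pixels are `NA` with `valid = FALSE`.
#'
#' @param mesh A `trimesh` with outward-facing normals.
#' @param pose An `ortho_pose` from [estimate_pose()].
#' @param dim Image size `c(lines, samples)`.
#' @param normals `"face"` (default) or `"vertex"`.
#' @return A `normal_map`: matrices `roll`, `pitch` (radians, `[-pi, pi]`)
#'   and logical `valid`.
#' @export
render_normals <- function(mesh, pose, dim, normals = c("face", "vertex")) {
  normals <- match.arg(normals)
  nr <- dim[1]; nc <- dim[2]
  pr <- project_mesh(mesh, pose)
  roll <- matrix(NA_real_, nr, nc)
  pitch <- matrix(NA_real_, nr, nc)
  zbuf <- matrix(-Inf, nr, nc)
  F <- mesh$faces
  A <- pr$cam[F[, 1], , drop = FALSE]
  B <- pr$cam[F[, 2], , drop = FALSE]
  C <- pr$cam[F[, 3], , drop = FALSE]
  fn <- cbind((B[, 2] - A[, 2]) * (C[, 3] - A[, 3]) - (B[, 3] - A[, 3]) * (C[, 2] - A[, 2]),
              (B[, 3] - A[, 3]) * (C[, 1] - A[, 1]) - (B[, 1] - A[, 1]) * (C[, 3] - A[, 3]),
              (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) - (B[, 2] - A[, 2]) * (C[, 1] - A[, 1]))
  # orient normals toward the camera (+z)
  flip <- fn[, 3] < 0
  fn[flip, ] <- -fn[flip, ]
  vn <- NULL
  if (normals == "vertex") {
    vn <- matrix(0, nrow(pr$cam), 3)
    for (k in 1:3) {
      vn[F[, k], ] <- vn[F[, k], ] + fn
    }
    vn <- vn / sqrt(rowSums(vn^2))
  }
  rows <- cbind(pr$row[F[, 1]], pr$row[F[, 2]], pr$row[F[, 3]])
  cols <- cbind(pr$col[F[, 1]], pr$col[F[, 2]], pr$col[F[, 3]])
  depth <- cbind(pr$cam[F[, 1], 3], pr$cam[F[, 2], 3], pr$cam[F[, 3], 3])
  any_drawn <- FALSE
  for (f in seq_len(nrow(F))) {
    r0 <- max(1L, ceiling(min(rows[f, ]))); r1 <- min(nr, floor(max(rows[f, ])))
    c0 <- max(1L, ceiling(min(cols[f, ]))); c1 <- min(nc, floor(max(cols[f, ])))
    if (r0 > r1 || c0 > c1) next
    px <- expand.grid(r = r0:r1, c = c0:c1)
    # barycentric coordinates in image space
    d <- (rows[f, 2] - rows[f, 3]) * (cols[f, 1] - cols[f, 3]) +
      (cols[f, 3] - cols[f, 2]) * (rows[f, 1] - rows[f, 3])
    if (abs(d) < 1e-12) next
    w1 <- ((rows[f, 2] - rows[f, 3]) * (px$c - cols[f, 3]) +
             (cols[f, 3] - cols[f, 2]) * (px$r - rows[f, 3])) / d
    w2 <- ((rows[f, 3] - rows[f, 1]) * (px$c - cols[f, 3]) +
             (cols[f, 1] - cols[f, 3]) * (px$r - rows[f, 3])) / d
    w3 <- 1 - w1 - w2
    inside <- w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9
    if (!any(inside)) next
    any_drawn <- TRUE
    pz <- w1 * depth[f, 1] + w2 * depth[f, 2] + w3 * depth[f, 3]
    sel <- which(inside)
    for (i in sel) {
      rr <- px$r[i]; cc <- px$c[i]
      if (pz[i] > zbuf[rr, cc]) {
        zbuf[rr, cc] <- pz[i]
        n <- if (normals == "face") fn[f, ] else {
          w1[i] * vn[F[f, 1], ] + w2[i] * vn[F[f, 2], ] + w3[i] * vn[F[f, 3], ]
        }
        roll[rr, cc] <- atan2(-n[1], n[3])
        pitch[rr, cc] <- atan2(n[2], n[3])
      }
    }
  }
  if (!any_drawn) {
    warn("pose projects the mesh entirely off-image: all pixels invalid")
  }
  structure(list(roll = roll, pitch = pitch, valid = !is.na(roll)),
            class = "normal_map")
}

#' @export
print.normal_map <- function(x, ...) {
  cat(sprintf("<normal_map> %d x %d, %.1f%% valid\n",
              nrow(x$roll), ncol(x$roll), 100 * mean(x$valid)))
  invisible(x)
}

#' Write / read a normal map as a two-page 32-bit float TIFF plus mask
#'
#' TIFF floats are stored in `[0, 1]`, so angles are encoded as
#' `(angle + pi) / (2 * pi)` on disk (page 1 roll, page 2 pitch) and
#' decoded on read; the validity mask travels alongside as
#' `<path>_valid.png`.
#'
#' @param nmap A `normal_map`.
#' @param path TIFF path.
#' @return `write_normal_tiff` invisibly returns `path`;
#'   `read_normal_tiff` returns a `normal_map`.
#' @export
write_normal_tiff <- function(nmap, path) {
  enc <- function(a) { a[!nmap$valid] <- 0; (a + pi) / (2 * pi) }
  tiff::writeTIFF(list(enc(nmap$roll), enc(nmap$pitch)), path,
                  bits.per.sample = 32L, reduce = FALSE)
  png::writePNG(nmap$valid * 1, sub("\\.tiff?$", "_valid.png", path))
  invisible(path)
}

#' @rdname write_normal_tiff
#' @export
read_normal_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  valid <- png::readPNG(sub("\\.tiff?$", "_valid.png", path)) > 0
  dec <- function(v) { a <- v * 2 * pi - pi; a[!valid] <- NA_real_; a }
  structure(list(roll = dec(pages[[1]]), pitch = dec(pages[[2]]),
                 valid = valid), class = "normal_map")
}

#' Bin sample spectra by surface-normal pitch
#'
#' Attaches to every sample the pitch of the surface normal at its window
#' center (nearest-pixel lookup), drops samples with invalid normals
#' (reporting the count), and summarises each pitch bin by per-band median
#' and median absolute deviation.
#'
#' @param samples Wide sample-set tibble with `row`, `col` columns.
#' @param nmap A `normal_map` on the same image grid.
#' @param bin_edges Increasing numeric vector of pitch bin edges (radians).
#' @return Long tibble: `bin` (label), `pitch_mid`, `pitch_mean`,
#'   `wavelength`, `median`, `mad`, `n`. Empty bins are omitted (with a
#'   warning).
#' @export
bin_by_pitch <- function(samples, nmap, bin_edges) {
  stopifnot(inherits(nmap, "normal_map"), length(bin_edges) >= 2,
            !is.unsorted(bin_edges, strictly = TRUE))
  m <- spectra_matrix(samples)
  wl <- attr(m, "wavelengths")
  pit <- nmap$pitch[cbind(samples$row, samples$col)]
  ok <- is.finite(pit)
  if (any(!ok)) {
    inform(sprintf("dropped %d sample(s) with invalid surface normals",
                   sum(!ok)), class = "avicube_invalid_normals")
  }
  m <- m[ok, , drop = FALSE]; pit <- pit[ok]
  bins <- cut(pit, breaks = bin_edges, include.lowest = TRUE)
  empty <- setdiff(levels(bins), unique(as.character(bins)))
  if (length(empty)) {
    warn(sprintf("empty pitch bin(s) omitted: %s",
                 paste(empty, collapse = ", ")))
  }
  mids <- (head(bin_edges, -1) + bin_edges[-1]) / 2
  out <- list()
  for (b in which(levels(bins) %in% unique(as.character(bins)))) {
    sel <- which(as.integer(bins) == b)
    sub <- m[sel, , drop = FALSE]
    out[[length(out) + 1]] <- tibble(
      bin = levels(bins)[b], pitch_mid = mids[b], pitch_mean = mean(pit[sel]),
      wavelength = wl,
      median = unname(apply(sub, 2, median)),
      mad = unname(apply(sub, 2, mad)),
      n = length(sel))
  }
  dplyr::bind_rows(out)
}
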