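random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("pose estimation recovers identity and synthetic transforms", {
  set.seed(51)
  P <- matrix(rnorm(15), 5, 3)                 # non-coplanar landmarks
  # identity pose: image coords straight from mesh x/y
  lm0 <- tibble::tibble(row = -P[, 2], col = P[, 1],
                        X = P[, 1], Y = P[, 2], Z = P[, 3])
  pose0 <- estimate_pose(lm0)
  expect_equal(pose0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(pose0$scale, 1, tolerance = 1e-10)
  expect_equal(unname(pose0$translation), c(0, 0), tolerance = 1e-10)
  expect_lt(pose0$rmse, 1e-10)

  for (i in 1:10) {
    R <- random_rotation(); s <- runif(1, 0.5, 40); t <- rnorm(2, sd = 20)
    cam <- P %*% t(R)
    lm <- tibble::tibble(row = -(s * cam[, 2] + t[2]),
                         col = s * cam[, 1] + t[1],
                         X = P[, 1], Y = P[, 2], Z = P[, 3])
    pose <- estimate_pose(lm)
    expect_lt(max(abs(pose$rotation - R)), 1e-8)
    expect_lt(abs(pose$scale - s), 1e-8)
    expect_lt(max(abs(pose$translation - t)), 1e-8)
    expect_lt(pose$rmse, 1e-8)
  }
})

test_that("pose residuals scale with landmark pixel noise", {
  set.seed(52)
  P <- matrix(rnorm(60), 20, 3)
  R <- random_rotation(); s <- 25
  cam <- P %*% t(R)
  rmse <- sapply(c(0.1, 1), function(sd) {
    lm <- tibble::tibble(row = -(s * cam[, 2]) + rnorm(20, sd = sd),
                         col = s * cam[, 1] + rnorm(20, sd = sd),
                         X = P[, 1], Y = P[, 2], Z = P[, 3])
    estimate_pose(lm)$rmse
  })
  expect_lt(rmse[1], 0.2)
  expect_gt(rmse[2] / rmse[1], 3)             # ~sigma scaling
})

test_that("degenerate landmark configurations are rejected", {
  lin <- tibble::tibble(row = 1:3, col = 1:3,
                        X = 1:3, Y = 2 * (1:3), Z = 3 * (1:3))
  expect_error(estimate_pose(lin), class = "avicube_error_degenerate")
  expect_error(estimate_pose(lin[1:2, ]), class = "avicube_error_value")
  expect_error(estimate_pose(tibble::tibble(row = 1, col = 1)),
               class = "avicube_error_format")
})

test_that("planes render constant roll/pitch at the expected angles", {
  # square plane facing the camera, z = 0
  v <- rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0))
  mesh <- trimesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
  pose <- identity_pose(scale = 20, center_col = 25, center_row = 25)
  nm <- render_normals(mesh, pose, c(50, 50))
  expect_gt(mean(nm$valid), 0.5)
  expect_equal(max(abs(nm$roll[nm$valid])), 0)
  expect_equal(max(abs(nm$pitch[nm$valid])), 0)

  # plane tilted 30 degrees about the vertical axis: |roll| = pi/6, pitch = 0
  th <- pi / 6
  Ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  mesh2 <- trimesh(v %*% t(Ry), rbind(c(1, 2, 3), c(1, 3, 4)))
  nm2 <- render_normals(mesh2, pose, c(50, 50))
  expect_equal(unique(round(abs(nm2$roll[nm2$valid]), 10)), round(th, 10))
  expect_equal(max(abs(nm2$pitch[nm2$valid])), 0, tolerance = 1e-10)
})

test_that("sphere normals match the closed form away from the silhouette", {
  mesh <- sphere_mesh(192, 96)
  pose <- identity_pose(scale = 40, center_col = 48, center_row = 48)
  nm <- render_normals(mesh, pose, c(96, 96), normals = "vertex")
  idx <- which(nm$valid, arr.ind = TRUE)
  x <- (idx[, 2] - 48) / 40
  y <- -(idx[, 1] - 48) / 40
  d2 <- x^2 + y^2
  keep <- d2 < 0.95^2                          # exclude 5% silhouette band
  z <- sqrt(pmax(1 - d2, 0))
  n_render <- cbind(-tan(nm$roll[idx]), tan(nm$pitch[idx]), 1)
  n_render <- n_render / sqrt(rowSums(n_render^2))
  ang <- acos(pmin(rowSums(n_render * cbind(x, y, z)), 1)) * 180 / pi
  expect_lt(max(ang[keep]), 1)
})

test_that("off-image poses warn and return an all-invalid map", {
  mesh <- sphere_mesh(16, 8)
  pose <- identity_pose(scale = 5, center_col = 500, center_row = 500)
  expect_warning(nm <- render_normals(mesh, pose, c(20, 20)), "off-image")
  expect_false(any(nm$valid))
})

test_that("pitch binning partitions samples and matches brute-force stats", {
  set.seed(53)
  # synthetic normal map with known pitch per column
  nr <- 40; nc <- 60
  pit <- matrix(rep(seq(-0.5, 0.5, length.out = nc), each = nr), nr, nc)
  nmap <- structure(list(roll = pit * 0, pitch = pit,
                         valid = matrix(TRUE, nr, nc)), class = "normal_map")
  m <- matrix(runif(50 * 4), 50, 4)
  ss <- wide_samples(m, c(400, 500, 600, 700))
  ss$row <- sample(nr, 50, replace = TRUE)
  ss$col <- sample(nc, 50, replace = TRUE)
  edges <- c(-0.6, -0.2, 0.2, 0.6)
  bb <- bin_by_pitch(ss, nmap, edges)
  expect_equal(sum(unique(bb[, c("bin", "n")])$n), 50)  # partition
  # brute-force per-bin median / MAD
  pv <- pit[cbind(ss$row, ss$col)]
  for (b in 1:3) {
    sel <- pv > edges[b] & pv <= edges[b + 1]
    if (b == 1) sel <- pv >= edges[1] & pv <= edges[2]
    if (!any(sel)) next
    sub <- bb[bb$pitch_mid == (edges[b] + edges[b + 1]) / 2, ]
    expect_equal(sub$median, apply(m[sel, , drop = FALSE], 2, median))
    expect_equal(sub$mad, apply(m[sel, , drop = FALSE], 2, mad))
  }
  # all samples at pitch 0 populate only the central bin
  nmap0 <- structure(list(roll = pit * 0, pitch = pit * 0,
                          valid = matrix(TRUE, nr, nc)), class = "normal_map")
  expect_warning(b0 <- bin_by_pitch(ss, nmap0, edges), "omitted")
  expect_equal(unique(b0$pitch_mid), 0)
  # invalid normals are dropped with a message
  nmap_na <- nmap
  nmap_na$pitch[, 1:30] <- NA
  nmap_na$valid[, 1:30] <- FALSE
  expect_message(suppressWarnings(bin_by_pitch(ss, nmap_na, edges)),
                 class = "avicube_invalid_normals")
})

test_that("OBJ meshes round-trip and polygons are triangulated", {
  mesh <- sphere_mesh(8, 4)
  path <- file.path(withr::local_tempdir(), "m.obj")
  write_obj(mesh, path)
  back <- read_obj(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-8)
  expect_equal(back$faces, mesh$faces)
  # quad + slash-form indices
  quad <- c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
            "f 1/1 2/2/2 3//3 4")
  p2 <- file.path(withr::local_tempdir(), "q.obj")
  writeLines(quad, p2)
  q <- read_obj(p2)
  expect_equal(nrow(q$faces), 2)
  expect_error(read_obj({p3 <- file.path(withr::local_tempdir(), "e.obj")
                         writeLines("v 0 0 0", p3); p3}),
               class = "avicube_error_format")
})

test_that("normal-map TIFFs round-trip roll/pitch and validity", {
  mesh <- sphere_mesh(32, 16)
  pose <- identity_pose(scale = 10, center_col = 16, center_row = 16)
  nm <- render_normals(mesh, pose, c(32, 32), normals = "face")
  path <- file.path(withr::local_tempdir(), "nm.tif")
  write_normal_tiff(nm, path)
  back <- read_normal_tiff(path)
  expect_equal(back$valid, nm$valid)
  expect_lt(max(abs(back$roll[nm$valid] - nm$roll[nm$valid])), 1e-6)
  expect_lt(max(abs(back$pitch[nm$valid] - nm$pitch[nm$valid])), 1e-6)
})
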