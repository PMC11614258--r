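test_that("PCA scores ignore overall brightness offsets", {
  set.seed(31)
  wl <- 300:700
  base <- matrix(runif(30 * 401, 0.2, 0.8), 30, 401)
  offs <- base + runif(30, -0.1, 0.1)        # per-spectrum constant offsets
  s1 <- pca_embed(wide_samples(base, wl), n_components = 10)
  s2 <- pca_embed(wide_samples(offs, wl), n_components = 10)
  m1 <- as.matrix(s1$scores[, paste0("pc", 1:10)])
  m2 <- as.matrix(s2$scores[, paste0("pc", 1:10)])
  expect_lt(max(abs(abs(m1) - abs(m2))), 1e-9)  # up to component sign
})

test_that("rank-2 data concentrates all variance in two components", {
  set.seed(32)
  wl <- 300:700
  u <- sin(wl / 50); v <- cos(wl / 90)
  coef <- matrix(rnorm(60), 30, 2)
  m <- 0.5 + 0.1 * (coef[, 1] %o% u + coef[, 2] %o% v)
  emb <- pca_embed(wide_samples(m, wl), n_components = 5,
                   center = "mean_spectrum")
  ev <- emb$explained_variance$all
  expect_lt(abs(sum(ev[1:2]) - 1), 1e-9)
  expect_true(all(diff(ev) <= 1e-12))          # non-increasing
  expect_true(all(ev >= 0 & ev <= 1))
})

test_that("group-wise PCA errors when a group is smaller than the rank", {
  wl <- 300:700
  m <- matrix(runif(12 * 401), 12, 401)
  ss <- wide_samples(m, wl, patch = rep(c("a", "b"), each = 6))
  expect_error(pca_embed(ss, n_components = 10, by = "patch"),
               class = "avicube_error_value")
  emb <- pca_embed(ss, n_components = 5, by = "patch")
  expect_named(emb$explained_variance, c("a", "b"))
})

test_that("manifold embedding is seed-deterministic and separates blobs", {
  set.seed(33)
  blob <- function(center, n) sweep(matrix(rnorm(n * 20, sd = 0.3), n, 20),
                                    2, center, `+`)
  X <- rbind(blob(rep(0, 20), 60), blob(rep(4, 20), 60))
  lab <- rep(1:2, each = 60)
  a <- manifold_embed(X, seed = 42)
  b <- manifold_embed(X, seed = 42)
  expect_identical(a, b)
  sil <- cluster::silhouette(lab, dist(a))
  expect_gt(mean(sil[, 3]), 0.5)
  # all-identical input collapses without crashing
  z <- manifold_embed(matrix(1, 12, 5), seed = 1)
  expect_true(all(z == 0))
  expect_error(manifold_embed(matrix(1, 5, 3)), class = "avicube_error_value")
})

test_that("HDR contour levels enclose the requested mass", {
  set.seed(34)
  n <- 4000
  coords <- tibble::tibble(x = rnorm(n), y = rnorm(n), g = "a")
  fld <- density_contours(coords, "g", mass = 0.8)
  cov <- avicube:::hdr_coverage(fld, coords, "g")
  expect_gt(cov, 0.74); expect_lt(cov, 0.86)
  full <- density_contours(coords, "g", mass = 1)
  expect_equal(unname(full$levels["a"]), 0)
  # normalisation: density integrates to ~1 on the grid
  cell <- diff(fld$x[1:2]) * diff(fld$y[1:2])
  expect_lt(abs(sum(fld$density$a) * cell - 1), 0.01)
})

test_that("disjoint groups get non-overlapping 80% contours", {
  set.seed(35)
  coords <- tibble::tibble(
    x = c(rnorm(300, 0, 0.3), rnorm(300, 10, 0.3)),
    y = c(rnorm(300, 0, 0.3), rnorm(300, 0, 0.3)),
    g = rep(c("a", "b"), each = 300))
  fld <- density_contours(coords, "g")
  inside_a <- fld$density$a >= fld$levels["a"]
  inside_b <- fld$density$b >= fld$levels["b"]
  expect_equal(sum(inside_a & inside_b), 0)
  expect_equal(nrow(fld$modes), 2)
  expect_lt(abs(fld$modes$x[fld$modes$group == "a"]), 0.5)
  expect_gt(fld$modes$x[fld$modes$group == "b"], 9)
})

test_that("mode spectra recover the generating spectrum of a tight cluster", {
  set.seed(36)
  wl <- 300:700
  truth <- 0.3 + 0.3 * exp(-((wl - 520)^2) / (2 * 40^2))
  noise_sd <- 0.01
  m <- matrix(rep(truth, each = 80), 80, 401) +
    matrix(rnorm(80 * 401, sd = noise_sd), 80, 401)
  ss <- wide_samples(m, wl)
  emb <- manifold_embed(pca_embed(ss, n_components = 10), seed = 1)
  fld <- density_contours(emb$scores, "patch")
  ms <- mode_spectra(fld, emb$scores, ss, "patch", k = 50)
  expect_equal(unique(ms$n), 50)
  expect_lt(max(abs(ms$median - truth)), 2 * noise_sd)
  # k = 1 picks the single nearest sample
  one <- mode_spectra(fld, emb$scores, ss, "patch", k = 1)
  expect_true(all(one$mad == 0))
  expect_warning(mode_spectra(fld, emb$scores, ss, "patch", k = 200),
                 "capped")
})

test_that("tidiers summarise the embedding object", {
  set.seed(37)
  m <- matrix(runif(30 * 401), 30, 401)
  emb <- manifold_embed(pca_embed(wide_samples(m, 300:700), 5), seed = 2)
  td <- tidy(emb)
  expect_true(all(c("patch", "pc1", "x", "y") %in% names(td)))
  gl <- glance(emb)
  expect_equal(gl$n, 30)
  expect_true(gl$has_map)
})
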