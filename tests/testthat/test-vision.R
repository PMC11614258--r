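test_that("pigment templates peak at lambda_max, normalised to 1", {
  for (lm in seq(400, 600, by = 25)) {
    s <- pigment_template(lm, 300:700)
    expect_equal(max(s), 1)
    expect_lte(abs((300:700)[which.max(s)] - lm), 1)
    expect_true(all(s >= 0))
  }
  expect_error(pigment_template(250), class = "avicube_error_value")
})

test_that("the average-VS system has ordered peaks covering 300-700", {
  rec <- vs_bird_receptors()
  sens <- rec$sensitivities
  expect_equal(range(sens$wavelength), c(300, 700))
  peaks <- sapply(c("vs", "sws", "mws", "lws"),
                  function(cn) sens$wavelength[which.max(sens[[cn]])])
  expect_true(all(diff(peaks) > 0))
  expect_equal(unname(rec$abundances), c(1, 1, 1, 2))
  expect_true("dbl" %in% names(sens))
  # receptor CSV round-trip through the source= path
  path <- file.path(withr::local_tempdir(), "rec.csv")
  utils::write.csv(sens, path, row.names = FALSE)
  rec2 <- vs_bird_receptors(source = path)
  expect_equal(rec2$sensitivities$mws, sens$mws, tolerance = 1e-8)
})

test_that("quantum catches normalise to 1 for a perfect white", {
  rec <- vs_bird_receptors()
  white <- tibble::tibble(wavelength = 300:700, reflectance = rep(1, 401))
  qc <- quantum_catch(white, rec)
  expect_equal(unname(unlist(qc[paste0("Q_", c("vs", "sws", "mws", "lws"))])),
               rep(1, 4))
  expect_equal(unname(unlist(qc[paste0("q_", c("vs", "sws", "mws", "lws"))])),
               rep(0.25, 4))
  expect_equal(c(qc$x, qc$y, qc$z), c(0, 0, 0))
  gray <- tibble::tibble(wavelength = 300:700, reflectance = rep(0.5, 401))
  qg <- quantum_catch(gray, rec)
  expect_equal(qg$Q_lws, 0.5)
  expect_equal(qg$q_lws, 0.25)        # brightness-invariant chromaticity
})

test_that("narrow-band stimuli load the expected receptor", {
  rec <- vs_bird_receptors()
  box <- tibble::tibble(wavelength = 300:700,
                        reflectance = as.numeric(abs(300:700 - 607) <= 5))
  qc <- quantum_catch(box, rec)
  qs <- unlist(qc[paste0("q_", c("vs", "sws", "mws", "lws"))])
  expect_equal(names(which.max(qs)), "q_lws")
  # direct-summation oracle for the catch itself
  S <- rec$sensitivities$lws
  expect_equal(qc$Q_lws, sum(box$reflectance * S) / sum(S))
})

test_that("tetrahedral coordinates place the center and vertices correctly", {
  expect_equal(unlist(tetra_coords(rep(0.25, 4))), c(x = 0, y = 0, z = 0))
  verts <- diag(4)
  xyz <- tetra_coords(verts)
  r <- sqrt(xyz$x^2 + xyz$y^2 + xyz$z^2)
  expect_equal(r, rep(0.75, 4), tolerance = 1e-12)
  expect_equal(xyz$z[1], 0.75)                 # VS vertex on +z
  # every simplex point stays within the vertex radius
  set.seed(41)
  q <- matrix(stats::rexp(400), 100, 4); q <- q / rowSums(q)
  xyz2 <- tetra_coords(q)
  expect_true(all(xyz2$x^2 + xyz2$y^2 + xyz2$z^2 <= 0.75^2 + 1e-12))
  expect_error(tetra_coords(c(0.5, 0.5, 0.2, 0.2)),
               class = "avicube_error_value")
})

test_that("chromatic contrast obeys the receptor-noise contracts", {
  rec <- vs_bird_receptors()
  set.seed(42)
  QA <- runif(4, 0.05, 1)
  expect_equal(rnl_chromatic(QA, QA, rec), 0)
  # brightness invariance and symmetry
  QB <- runif(4, 0.05, 1)
  expect_equal(rnl_chromatic(QA, QB, rec), rnl_chromatic(QB, QA, rec))
  expect_equal(rnl_chromatic(QA * 3.7, QB, rec), rnl_chromatic(QA, QB, rec))
  expect_equal(rnl_chromatic(QA, QB * 0.2, rec), rnl_chromatic(QA, QB, rec))
  expect_error(rnl_chromatic(c(0, 1, 1, 1), QB, rec),
               class = "avicube_error_value")
})

test_that("dS matches an independent formulation on random catch pairs", {
  rec <- vs_bird_receptors(abundances = c(vs = 1, sws = 1, mws = 1, lws = 2))
  e <- rec$weber * sqrt(max(rec$abundances) / rec$abundances)
  set.seed(43)
  worst <- 0
  for (i in 1:1000) {
    QA <- runif(4, 1e-3, 2); QB <- runif(4, 1e-3, 2)
    worst <- max(worst, abs(rnl_chromatic(QA, QB, rec) -
                              rnl_oracle(QA, QB, e)))
  }
  expect_lt(worst, 1e-10)
  # unequal-noise systems too
  rec2 <- vs_bird_receptors(abundances = c(vs = 0.5, sws = 1, mws = 3, lws = 2),
                            weber = 0.05)
  e2 <- rec2$weber * sqrt(max(rec2$abundances) / rec2$abundances)
  for (i in 1:200) {
    QA <- runif(4, 1e-3, 2); QB <- runif(4, 1e-3, 2)
    expect_lt(abs(rnl_chromatic(QA, QB, rec2) - rnl_oracle(QA, QB, e2)), 1e-10)
  }
})

test_that("luminance contrast follows the log-ratio Weber form", {
  rec <- vs_bird_receptors()
  expect_equal(rnl_luminance(0.4, 0.4, rec), 0)
  expect_equal(rnl_luminance(0.2, 0.4, rec), log(2) / 0.1)
  # scaling a reflectance spectrum by k gives dL = |ln k| / w via catches
  sp <- tibble::tibble(wavelength = 300:700,
                       reflectance = 0.2 + 0.3 * exp(-((300:700 - 550) / 60)^2))
  qa <- quantum_catch(sp, rec)
  qb <- quantum_catch(dplyr::mutate(sp, reflectance = reflectance * 1.5), rec)
  expect_equal(rnl_luminance(qa$Q_dbl, qb$Q_dbl, rec), log(1.5) / 0.1)
  expect_error(rnl_luminance(-1, 0.5, rec), class = "avicube_error_value")
})

test_that("the discriminability threshold is inclusive at 3", {
  expect_true(discriminable(3.0))
  expect_false(discriminable(2.999))
  expect_false(discriminable(0))
  expect_equal(discriminable(c(0, 3, 10), threshold = 3),
               c(FALSE, TRUE, TRUE))
})

test_that("patch contrasts compare specimen medians pairwise", {
  wl <- 300:700
  spA <- 0.1 + 0.5 * exp(-((wl - 520) / 40)^2)
  spB <- 0.1 + 0.5 * exp(-((wl - 620) / 40)^2)
  m <- rbind(matrix(rep(spA, each = 20), 20, 401),
             matrix(rep(spB, each = 20), 20, 401))
  ss <- wide_samples(m, wl)
  ss$specimen <- rep(c("s1", "s2"), each = 20)
  rec <- vs_bird_receptors()
  ct <- patch_contrasts(ss, rec)
  expect_equal(nrow(ct), 1)
  expect_gt(ct$dS, 3)                       # green vs red: clearly discriminable
  expect_true(ct$discriminable_dS)
  # identical specimens -> zero contrast
  ss$specimen <- rep(c("s1", "s2"), 20)
  ct0 <- patch_contrasts(ss, rec)
  expect_equal(ct0$dS + ct0$dL, 0)
})

test_that("cone-catch images agree with per-spectrum catches patch-wise", {
  sim <- simulate_cube(scene_spec(noise_sd = 0, gradient = 0, seed = 6))
  ff <- flat_field(sim$cube, sim$bright)
  rec <- vs_bird_receptors()
  img <- cone_catch_image(ff, rec, extend = "constant")
  expect_equal(dim(img)[3], 5)
  expect_equal(dimnames(img)[[3]], c("vs", "sws", "mws", "lws", "dbl"))
  for (p in c("breast", "back")) {
    truth <- sim$truth$spectra[[p]]
    grid <- interpolate_1nm(truth)
    full <- tibble::tibble(
      wavelength = 300:700,
      reflectance = c(rep(grid$reflectance[1], 25), grid$reflectance))
    qc <- quantum_catch(full, rec)
    idx <- which(sim$masks[[p]], arr.ind = TRUE)
    for (ch in c("vs", "lws")) {
      got <- mean(img[, , ch][idx])
      expect_lt(abs(got - qc[[paste0("Q_", ch)]]), 1e-6)
    }
  }
  # channel count without a double cone
  rec4 <- vs_bird_receptors(double_cone = "none")
  img4 <- cone_catch_image(ff, rec4)
  expect_equal(dim(img4)[3], 4)
  # refusal on uncalibrated radiance
  expect_error(suppressWarnings(cone_catch_image(sim$cube, rec)),
               class = "avicube_error_value")
  path <- file.path(withr::local_tempdir(), "cc.tif")
  write_cone_tiff(img, path)
  back <- tiff::readTIFF(path, all = TRUE)
  expect_length(back, 5)
  expect_equal(back[[4]], img[, , "lws"], tolerance = 1e-6)
})
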