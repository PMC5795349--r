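# Four-band toy cubes at the index wavelengths make every spectral
# operation hand-checkable.
four_band <- function(r705, r750, r1056, r1151) {
  toy_cube(list(`705` = r705, `750` = r750,
                `1056` = r1056, `1151` = r1151))
}

test_that("cube write/read round-trips bit-exactly", {
  set.seed(1)
  planes <- array(sample(0:255, 6 * 5 * 4, replace = TRUE) / 255,
                  c(6, 5, 4))
  cube <- hyper_cube(planes, c(546, 900, 1200, 1700))
  dir <- withr::local_tempdir()
  write_cube(cube, dir)
  back <- read_cube(dir)
  expect_identical(back$planes, cube$planes)
  expect_equal(back$wavelengths, cube$wavelengths, tolerance = 0.01)
})

test_that("a missing band file is reported by index", {
  cube <- hyper_cube(array(0.5, c(3, 3, 5)), seq(600, 1000, 100))
  dir <- withr::local_tempdir()
  write_cube(cube, dir)
  file.remove(list.files(dir, pattern = "band_003", full.names = TRUE))
  expect_error(read_cube(dir), "missing band file.*3")
})

test_that("3-channel grayscale band files are accepted; mixed ones are not", {
  dir <- withr::local_tempdir()
  gray <- matrix(runif(20), 4, 5)
  gray <- round(gray * 255) / 255
  png::writePNG(array(rep(gray, 3), c(4, 5, 3)),
                file.path(dir, "band_001_00600.00nm.png"))
  png::writePNG(gray, file.path(dir, "band_002_00700.00nm.png"))
  cube <- read_cube(dir)
  expect_equal(dim(cube$planes), c(4L, 5L, 2L))
  expect_identical(cube$planes[, , 1], cube$planes[, , 2])

  bad <- array(runif(60), c(4, 5, 3))
  png::writePNG(bad, file.path(dir, "band_003_00800.00nm.png"))
  expect_error(read_cube(dir), "not grayscale")
})

test_that("nearest-band lookup matches the uniform-grid arithmetic", {
  wl <- seq(546, 1700, length.out = 243)
  cube <- hyper_cube(array(0, c(1, 1, 243)), wl)
  expect_equal(band_for_wavelength(cube, 546), 1L)
  expect_equal(band_for_wavelength(cube, 1700), 243L)
  # (705 - 546) / 4.7686 = 33.34 -> 34th band, 1-based
  expect_equal(band_for_wavelength(cube, 705), 34L)
  expect_lte(abs(wl[34] - 705), diff(wl)[1] / 2)
  expect_error(band_for_wavelength(cube, 500), "outside")
  # tie breaks toward the lower index
  tie <- hyper_cube(array(0, c(1, 1, 2)), c(700, 710))
  expect_equal(band_for_wavelength(tie, 705), 1L)
})

test_that("NDVI segmentation matches hand evaluation and strictness", {
  one <- function(v) matrix(v, 2, 2)
  cube <- four_band(one(0.2), one(0.5), one(0.4), one(0.4))
  nd <- ndvi_map(cube)
  expect_equal(nd[1, 1], 0.3 / 0.7)
  expect_false(is_na_mask(segment_plant_ndvi(cube)))

  # symmetric bands -> NDVI 0 -> background
  cube0 <- four_band(one(0.5), one(0.5), one(0), one(0))
  expect_equal(ndvi_map(cube0)[1, 1], 0)
  expect_true(is_na_mask(segment_plant_ndvi(cube0)))

  # reversed bands -> negative NDVI -> background
  cube_neg <- four_band(one(0.5), one(0.2), one(0), one(0))
  expect_equal(ndvi_map(cube_neg)[1, 1], -0.3 / 0.7)
  expect_true(is_na_mask(segment_plant_ndvi(cube_neg)))

  # zero denominator defined as 0
  cube00 <- four_band(one(0), one(0), one(0), one(0))
  expect_equal(ndvi_map(cube00)[1, 1], 0)

  # NDVI bounded for non-negative intensities
  set.seed(3)
  rc <- four_band(matrix(runif(4), 2), matrix(runif(4), 2),
                  one(0.1), one(0.1))
  expect_true(all(ndvi_map(rc) >= -1 & ndvi_map(rc) <= 1))
})

test_that("stem/leaf separation is a strict-ratio partition of the plant", {
  one <- function(v) matrix(v, 2, 3)
  # ratio 1.3 -> stem; ratio 1.0 -> leaf; threshold value itself -> leaf
  for (r in list(c(1.3, 1.0, TRUE), c(1.0, 1.0, FALSE),
                 c(1.2, 1.0, FALSE))) {
    cube <- four_band(one(0.2), one(0.5), one(r[1] / 5), one(r[2] / 5))
    plant <- segment_plant_ndvi(cube)
    sl <- segment_stem(cube, plant)
    expect_equal(all(sl$stem[plant]), as.logical(r[3]))
    expect_equal(sl$stem | sl$leaf, plant, ignore_attr = TRUE)
    expect_false(any(sl$stem & sl$leaf))
  }
  # R1151 = 0 with R1056 > 0 counts as stem
  cube <- four_band(one(0.2), one(0.5), one(0.4), one(0))
  sl <- segment_stem(cube, segment_plant_ndvi(cube))
  expect_true(all(sl$stem))
})

test_that("background normalization divides by the per-band background mean", {
  pl <- matrix(2, 3, 3); pl[2, 2] <- 3  # plant pixel 3.0, background 2.0
  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  cube <- hyper_cube(array(pl, c(3, 3, 1)) , 1000)
  norm <- normalize_cube(cube, mask)
  expect_equal(norm$planes[2, 2, 1], 1.5)
  expect_equal(norm$planes[1, 1, 1], 2)  # background passes through
  expect_true(norm$normalized)

  # plant pixel equal to the background mean -> exactly 1
  pl2 <- matrix(2, 3, 3)
  cube2 <- hyper_cube(array(pl2, c(3, 3, 1)), 1000)
  expect_equal(normalize_cube(cube2, mask)$planes[2, 2, 1], 1)

  # zero-background band is an error naming the band
  cube3 <- hyper_cube(array(0, c(3, 3, 2)), c(800, 900))
  expect_error(normalize_cube(cube3, mask), "band 1")
})

test_that("normalized plant values are invariant to global illumination", {
  set.seed(11)
  planes <- array(runif(5 * 4 * 3, 0.1, 0.9), c(5, 4, 3))
  cube <- hyper_cube(planes, c(700, 1000, 1300))
  mask <- matrix(FALSE, 5, 4); mask[2:3, 2:3] <- TRUE
  n1 <- normalize_cube(cube, mask)
  n2 <- normalize_cube(hyper_cube(planes * 3.7, cube$wavelengths), mask)
  for (b in 1:3) {
    expect_equal(n1$planes[, , b][mask], n2$planes[, , b][mask])
  }
})

test_that("min-max false-colour mapping reproduces the 3-score fixture", {
  # three plant pixels whose single varying band yields PC1 scores in
  # arithmetic progression -> rescaled channel {0, 0.5, 1} -> {0,128,255}
  planes <- array(0.5, c(1, 3, 2))
  planes[1, , 1] <- c(0.2, 0.4, 0.6)
  cube <- hyper_cube(planes, c(700, 1000))
  mask <- matrix(TRUE, 1, 3)
  # the second component is constant here, which warns by design
  expect_warning(img <- pca_false_color(cube, mask), "constant")
  red <- sort(img[1, , 1])
  expect_equal(red, c(0, 128, 255))  # round-half-up quantization of 0.5
  expect_true(all(img >= 0 & img <= 255))
})

test_that("constant components render as zero channels with a warning", {
  planes <- array(0.4, c(2, 3, 3))
  cube <- hyper_cube(planes, c(700, 1000, 1300))
  mask <- matrix(TRUE, 2, 3)
  w <- capture_warnings(img <- pca_false_color(cube, mask))
  expect_true(all(grepl("constant", w)))
  expect_gte(length(w), 2L)
  expect_true(all(img == 0))
})

test_that("PC1 separates stem from leaf spectra on a two-cluster cube", {
  cfg <- synth_config(seed = 4, illumination_drift_sd = 0)
  d <- generate_design(0)
  hy <- render_hypercube(d, "001", 22, "side0", cfg)
  plant <- segment_plant_ndvi(hy$cube)
  sl <- segment_stem(hy$cube, plant)
  norm <- normalize_cube(hy$cube, plant)
  img <- pca_false_color(norm, plant)
  red <- img[, , 1]
  expect_gt(abs(mean(red[sl$stem]) - mean(red[sl$leaf])), 10)

  # independent oracle: PC1 from a direct eigen-decomposition of the
  # plant-pixel covariance gives the same between-tissue separation
  nb <- dim(norm$planes)[3]
  X <- sapply(seq_len(nb), function(b) norm$planes[, , b][plant])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  v1 <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)$vectors[, 1]
  s1 <- drop(Xc %*% v1)
  lab <- sl$stem[plant]
  expect_gt(abs(mean(s1[lab]) - mean(s1[!lab])) / stats::sd(s1), 1)
})

test_that("full-rank PCA reconstruction is lossless (eigen oracle)", {
  set.seed(9)
  X <- matrix(runif(60), 12, 5)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  Xhat <- sweep(pc$x %*% t(pc$rotation), 2, pc$center, `+`)
  expect_equal(Xhat, X, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("mean spectra average masked pixels per band", {
  planes <- array(0, c(2, 2, 2))
  planes[, , 1] <- matrix(c(1, 3, 5, 7), 2)
  planes[, , 2] <- 0.5
  cube <- hyper_cube(planes, c(700, 1000))
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  sp <- mean_spectrum(cube, mask, "leaf")
  expect_equal(sp$mean_intensity, c(2, 0.5))
  expect_equal(sp$n_pixels, c(2L, 2L))
  expect_equal(sp$tissue, c("leaf", "leaf"))
  expect_error(mean_spectrum(cube, matrix(FALSE, 2, 2)), "non-empty")
})

test_that("phantom stem spectra are brighter at 1056 than 1151 nm", {
  cfg <- synth_config(seed = 2, illumination_drift_sd = 0)
  d <- generate_design(0)
  hy <- render_hypercube(d, "003", 20, "side0", cfg)
  plant <- segment_plant_ndvi(hy$cube)
  sl <- segment_stem(hy$cube, plant)
  stem_sp <- mean_spectrum(hy$cube, sl$stem, "stem")
  b1056 <- band_for_wavelength(hy$cube, 1056)
  b1151 <- band_for_wavelength(hy$cube, 1151)
  expect_gt(stem_sp$mean_intensity[b1056], stem_sp$mean_intensity[b1151])
})
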