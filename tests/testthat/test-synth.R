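# The generator is the oracle for every downstream stage, so these tests
# exercise its contracts: determinism, truth-mask identity, threshold
# margins, and the degenerate variance cases.

design0 <- generate_design(0)
quiet_cfg <- synth_config(seed = 3, illumination_drift_sd = 0)

test_that("configuration validation rejects inconsistent settings", {
  expect_error(synth_config(band_count = 1), "band_count")
  expect_error(synth_config(wavelength_range_nm = c(1700, 546)),
               "increasing")
  expect_error(synth_config(genotype_variance = -1), "non-negative")
  expect_error(synth_config(zoom_schedule = rep(3L, 29)), "zoom")
  expect_equal(length(config_wavelengths(synth_config())), 243L)
})

test_that("trait panel follows the additive model and its seed", {
  p1 <- simulate_trait_panel(design0, quiet_cfg)
  p2 <- simulate_trait_panel(design0, quiet_cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 156L * 29L)

  # all-zero variances: every plant identical on every day
  flat <- simulate_trait_panel(
    design0, synth_config(seed = 1, genotype_variance = 0,
                          row_variance = 0, error_variance = 0))
  per_day <- tapply(flat$height_px, flat$day,
                    function(v) length(unique(v)))
  expect_true(all(per_day == 1L))
  # growth: the mean curve increases with day
  mu <- tapply(flat$height_px, flat$day, mean)
  expect_true(all(diff(mu) > 0))
})

test_that("rendered scenes recover their truth masks exactly", {
  set.seed(101)
  panel <- simulate_trait_panel(design0, quiet_cfg)
  pots <- sample(design0$pot_id[!design0$is_empty], 6)
  for (pid in pots) {
    day <- sample(15:29, 1)
    for (view in c("side0", "side90", "top")) {
      sc <- render_rgb_scene(design0, pid, day, view, quiet_cfg, panel)
      m <- segment_plant(sc$image)
      expect_identical(unname(which(m)), unname(which(sc$truth$plant)))
      geo <- extract_geometry(m, zoom_calibration(), day)
      expect_equal(geo$height_px, sc$truth$height_px)
      expect_equal(geo$width_px, sc$truth$width_px)
      expect_equal(geo$area_px, sc$truth$area_px)
    }
    fl <- render_fluorescence_image(design0, pid, 20, "side0",
                                    quiet_cfg, panel)
    fm <- segment_fluorescence(fl$image)
    expect_identical(unname(which(fm)), unname(which(fl$truth$plant)))
  }
})

test_that("truth bounding boxes equal the planted trait values", {
  panel <- simulate_trait_panel(design0, quiet_cfg)
  tr <- panel[panel$pot_id == "001" & panel$day == 22, ]
  sc <- render_rgb_scene(design0, "001", 22, "side0", quiet_cfg, panel)
  expect_equal(sc$truth$height_px, round(tr$height_px))
  expect_equal(sc$truth$width_px, round(tr$width_px))
})

test_that("pre-emergence days and empty pots segment to NA", {
  sc <- render_rgb_scene(design0, "001", 1, "side0", quiet_cfg)
  expect_true(is_na_mask(segment_plant(sc$image)))
  expect_equal(sc$truth$area_px, 0L)

  empty_pot <- design0$pot_id[design0$is_empty][1]
  sc2 <- render_rgb_scene(design0, empty_pot, 20, "side0", quiet_cfg)
  expect_false(any(sc2$truth$plant))
  expect_true(is_na_mask(segment_plant(sc2$image)))
  fl <- render_fluorescence_image(design0, empty_pot, 20, "side0",
                                  quiet_cfg)
  expect_true(all(fl$image[, , 1] <= 70))
})

test_that("hypercubes have the configured grid and seeded illumination", {
  hy <- render_hypercube(design0, "001", 20, "side0", quiet_cfg)
  expect_equal(dim(hy$cube$planes)[3], 243L)
  expect_equal(hy$cube$wavelengths[1], 546)
  expect_equal(hy$cube$wavelengths[243], 1700)

  # zero drift: renders are bit-identical
  h2 <- render_hypercube(design0, "001", 20, "side0", quiet_cfg)
  expect_identical(hy$cube$planes, h2$cube$planes)

  # with drift, same seed gives same cube; masks survive the scaling
  drift_cfg <- synth_config(seed = 3, illumination_drift_sd = 0.15)
  d1 <- render_hypercube(design0, "001", 20, "side0", drift_cfg)
  d2 <- render_hypercube(design0, "001", 20, "side0", drift_cfg)
  expect_identical(d1$cube$planes, d2$cube$planes)
  pm <- segment_plant_ndvi(d1$cube)
  expect_identical(unname(which(pm)), unname(which(d1$truth$plant)))
  sl <- segment_stem(d1$cube, pm)
  expect_identical(unname(which(sl$stem)), unname(which(d1$truth$stem)))
  expect_identical(unname(which(sl$leaf)), unname(which(d1$truth$leaf)))
})

test_that("truth stem and leaf partition the plant mask", {
  hy <- render_hypercube(design0, "005", 25, "side0", quiet_cfg)
  expect_equal(hy$truth$stem | hy$truth$leaf, hy$truth$plant)
  expect_false(any(hy$truth$stem & hy$truth$leaf))
})

test_that("biomass truth is proportional to area under equal densities", {
  areas <- data.frame(pot_id = sprintf("%03d", 1:6),
                      genotype = rep(c("ZL1", "ZL2"), 3),
                      area_adj = c(100, 200, 300, 400, 500, 600))
  cfg_eq <- synth_config(
    density_by_genotype = c(ZL1 = 0.01, ZL2 = 0.01), biomass_noise_sd = 0)
  bm <- simulate_biomass_truth(areas, cfg_eq)
  expect_equal(bm$fresh_biomass_g, 0.01 * areas$area_adj)

  expect_error(
    simulate_biomass_truth(areas,
                           synth_config(density_by_genotype = c(ZL1 = 1))),
    "ZL2")
})

test_that("the default density map covers the full seed-0 design", {
  cfg <- synth_config(seed = 0, biomass_noise_sd = 0)
  plants <- design0[!design0$is_empty, ]
  areas <- data.frame(pot_id = plants$pot_id, genotype = plants$genotype,
                      area_adj = 1000)
  bm <- simulate_biomass_truth(areas, cfg)
  expect_equal(nrow(bm), 156L)
  expect_true(all(is.finite(bm$fresh_biomass_g)))
})
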