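test_that("one-way ANOVA fixtures match hand-computed sums of squares", {
  obs <- data.frame(genotype = c("A", "A", "B", "B"), value = c(1, 1, 3, 3))
  fit <- anova_day(obs, "genotype_only")
  expect_equal(fit$ss_genotype, 4)
  expect_equal(fit$ss_error, 0)
  expect_equal(heritability(fit, "classical"), 1)

  obs2 <- data.frame(genotype = c("A", "A", "B", "B"), value = c(0, 2, 2, 4))
  fit2 <- anova_day(obs2, "genotype_only")
  expect_equal(fit2$ss_genotype, 4)
  expect_equal(fit2$ss_error, 4)
  expect_equal(heritability(fit2, "classical"), 0.5)
  # the adjusted ratio on a genotype-only fit is SSg/(SSg+SSe) too
  expect_equal(heritability(fit2, "adjusted"), 0.5)

  allsame <- data.frame(genotype = c("A", "A", "B", "B"), value = rep(2, 4))
  fit3 <- anova_day(allsame, "genotype_only")
  expect_equal(fit3$ss_genotype + fit3$ss_error, 0)
  expect_warning(h <- heritability(fit3, "classical"), "zero|undefined")
  expect_true(is.na(h))
})

test_that("row adjustment removes positional variance from the denominator", {
  # two rows offset by +10, genotypes differing by 2 within each row
  obs <- data.frame(
    row = c(1, 1, 2, 2), genotype = c("A", "B", "A", "B"),
    value = c(0, 2, 10, 12))
  adj <- anova_day(obs, "row_genotype")
  expect_equal(adj$ss_env, 100)     # 2*(5-6)^2*... hand: rows 1,11 about 6
  expect_equal(adj$ss_genotype, 4)
  expect_equal(adj$ss_error, 0, tolerance = 1e-12)
  expect_equal(adj$ss_total, adj$ss_env + adj$ss_genotype + adj$ss_error)
  expect_equal(heritability(adj, "adjusted"), 1)

  cls <- anova_day(obs, "genotype_only")
  expect_equal(heritability(cls, "classical"), 4 / 104)
  expect_lt(heritability(cls, "classical"), 1)
})

test_that("ANOVA preconditions and filters behave as documented", {
  expect_error(anova_day(data.frame(genotype = "A", value = 1),
                         "genotype_only"), "2 replicated genotypes")
  # unreplicated genotypes (the ZL22 situation) are dropped before fitting
  obs <- data.frame(genotype = c("A", "A", "B", "B", "Z"),
                    value = c(1, 2, 3, 4, 100),
                    row = c(1, 2, 1, 2, 1))
  fit <- anova_day(obs, "row_genotype")
  expect_equal(fit$n_genotypes, 2L)
  expect_equal(fit$n_obs, 4L)
  expect_equal(fit$n_dropped, 1L)
  # NA values are dropped per day (A keeps two replicates here)
  obs2 <- data.frame(genotype = c("A", "A", "A", "B", "B"),
                     value = c(NA, 2, 3, 4, 5))
  fit2 <- anova_day(obs2, "genotype_only")
  expect_equal(fit2$n_obs, 4L)
  expect_equal(fit2$n_dropped, 1L)
  expect_error(heritability(fit, "classical"), "genotype_only")
})

test_that("error heritability reproduces the hand fixtures", {
  # residuals perfectly determined by genotype, one replicate
  frac <- error_heritability(c(1, 1, -1, -1), c("A", "A", "B", "B"),
                             rep(1L, 4))
  expect_equal(frac, 1)

  # residuals that a saturated fit has zeroed out are undefined
  expect_warning(
    f0 <- error_heritability(rep(0, 8) + rnorm(8, 0, 1e-15),
                             rep(c("A", "B"), each = 4),
                             rep(1:4, 2)),
    "undefined")
  expect_true(is.na(f0))
})

test_that("iid-noise error fractions match the permutation-null oracle", {
  d <- generate_design(0)
  plants <- d[!d$is_empty & d$genotype != "ZL22", ]
  set.seed(33)
  sims <- vapply(1:60, function(i) {
    error_heritability(rnorm(nrow(plants)), plants$genotype,
                       plants$replicate)
  }, 0)
  perm <- perm_null_fractions(rnorm(nrow(plants)), plants$genotype,
                              plants$replicate, n = 60, seed = 34)
  # both are draws of the same null statistic
  expect_lt(abs(mean(sims) - mean(perm)), 0.03)
})

test_that("the smoother preserves constants, limits, and ranges", {
  days <- 1:7
  const <- smooth_heritability(days, rep(0.42, 7), bandwidth = 2)
  expect_equal(const$smoothed, rep(0.42, 7))

  raw <- c(0.1, 0.9, 0.3, 0.7, 0.2, 0.8, 0.5)
  tiny <- smooth_heritability(days, raw, bandwidth = 1e-9)
  expect_equal(tiny$smoothed, raw)

  sm <- smooth_heritability(days, raw, bandwidth = 2)
  expect_true(all(sm$smoothed >= min(raw) & sm$smoothed <= max(raw)))

  # hand kernel weights for {0, 1, 0} at days {1, 2, 3}, bandwidth 1:
  # centre value = 1 / (1 + 2 * exp(-1/2))
  spike <- smooth_heritability(1:3, c(0, 1, 0), bandwidth = 1)
  expect_equal(spike$smoothed[2], 1 / (1 + 2 * exp(-0.5)))
  expect_gt(spike$smoothed[2], 0); expect_lt(spike$smoothed[2], 1)

  expect_error(smooth_heritability(days, raw, bandwidth = 0), "positive")
  expect_error(smooth_heritability(1:2, c(0, 1)), "3 days")
})

test_that("per-day series have additive SS and bounded heritability", {
  d <- generate_design(0)
  cfg <- synth_config(seed = 9, genotype_variance = 60, row_variance = 30,
                      error_variance = 20)
  panel <- simulate_trait_panel(d, cfg)
  obs <- panel[panel$day %in% c(16, 20, 24, 28), ]
  obs$value <- obs$height_px
  ser <- heritability_series(obs, bandwidth = 2)
  expect_equal(nrow(ser), 4L)
  ok <- is.finite(ser$hr_adjusted)
  expect_true(all(ser$hr_adjusted[ok] >= 0 & ser$hr_adjusted[ok] <= 1))
  expect_true(all(ser$hr_classical[ok] >= 0 & ser$hr_classical[ok] <= 1))
  # SS additivity of the adjusted model, checked against a direct refit
  day16 <- obs[obs$day == 16, ]
  fit16 <- anova_day(day16, "row_genotype")
  expect_equal(fit16$ss_total,
               fit16$ss_env + fit16$ss_genotype + fit16$ss_error)
  expect_true(all(ser$hr_smoothed[ok] >=
                    min(ser$hr_adjusted[ok]) - 1e-12))
  expect_true(all(ser$hr_smoothed[ok] <=
                    max(ser$hr_adjusted[ok]) + 1e-12))
  # with positive row variance the adjusted ratio exceeds the classical
  expect_true(mean(ser$hr_adjusted[ok]) > mean(ser$hr_classical[ok]))
})
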