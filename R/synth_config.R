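#' Configuration for the synthetic phantom-plant experiment
#'
#' Bundles every tunable of the synthetic generator: imaging-day count,
#' hyperspectral band grid, trait variance components, genotype-specific
#' tissue densities, per-image illumination drift, zoom schedule, and
#' canvas sizes. Defaults emulate the greenhouse campaign the package
#' models: 29 daily imaging sessions, 243 spectral bands spanning
#' 546--1700 nm, and a 10 x 16 pot grid of 32 genotypes.
#'
#' @param seed Integer master seed; every random draw in the generator is a
#'   pure function of this seed plus the pot/day/view being rendered.
#' @param n_days Number of imaging days (default 29).
#' @param band_count Number of hyperspectral bands (default 243; must be
#'   at least 2).
#' @param wavelength_range_nm Length-2 increasing numeric vector giving the
#'   first and last band-centre wavelengths (default `c(546, 1700)`);
#'   bands are laid out on a uniform grid between them.
#' @param genotype_variance,row_variance,error_variance Variance components
#'   (squared pixels) of the growth-trait model: genotype effects are drawn
#'   once per genotype, row effects once per greenhouse row, and the error
#'   term independently per plant and day.
#' @param density_by_genotype Named numeric vector mapping genotype labels
#'   to tissue density in grams of fresh biomass per zoom-adjusted plant
#'   pixel. Default: a fixed spread from 0.010 to 0.014 g/px across
#'   `ZL1`..`ZL32`, emulating real leaf-to-stem ratio differences.
#' @param biomass_noise_sd Standard deviation (g) of the non-systematic
#'   part of fresh-biomass measurement (default 0: exact density model).
#' @param illumination_drift_sd Log-scale standard deviation of the
#'   per-image multiplicative illumination factor applied to hyperspectral
#'   cubes (lognormal, median 1; default 0.05). Set 0 for bit-reproducible
#'   cubes.
#' @param zoom_schedule Integer vector of length `n_days` of zoom levels
#'   (1 or 2) per imaging day. Default: all days at zoom 1. See
#'   [zoom_schedule_campaign()] for the campaign-style schedule with a
#'   mid-experiment zoom reduction.
#' @param canvas Integer `c(height, width)` of the synthetic RGB and
#'   fluorescence canvases (default `c(400, 300)`, far below the real
#'   2454 x 2056 sensor, for desk-scale tests; raise for full-size
#'   rendering).
#' @param hyper_canvas Canvas for hyperspectral cubes (default
#'   `c(100, 75)`; the phantom geometry is scaled down proportionally).
#' @param height_max_px,width_max_px Asymptotes of the logistic growth
#'   curves for plant height and width, in zoom-1 pixels on `canvas`.
#' @param emergence_px Minimum modelled height (px) for a plant to be
#'   rendered; below it the pot is imaged as bare soil and downstream
#'   segmentation reports `NA` (default 5).
#' @param plant_red,background_red Red-channel intensities used by the
#'   fluorescence renderer for plant and background pixels (defaults 200
#'   and 30; the segmentation threshold is 70).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 0L,
                         n_days = 29L,
                         band_count = 243L,
                         wavelength_range_nm = c(546, 1700),
                         genotype_variance = 100,
                         row_variance = 25,
                         error_variance = 25,
                         density_by_genotype = NULL,
                         biomass_noise_sd = 0,
                         illumination_drift_sd = 0.05,
                         zoom_schedule = NULL,
                         canvas = c(400L, 300L),
                         hyper_canvas = c(100L, 75L),
                         height_max_px = 280,
                         width_max_px = 150,
                         emergence_px = 5,
                         plant_red = 200,
                         background_red = 30) {
  if (band_count < 2L) stop("band_count must be at least 2")
  if (length(wavelength_range_nm) != 2L ||
      diff(wavelength_range_nm) <= 0) {
    stop("wavelength_range_nm must be strictly increasing")
  }
  if (any(c(genotype_variance, row_variance, error_variance) < 0)) {
    stop("variance components must be non-negative")
  }
  if (biomass_noise_sd < 0) stop("biomass_noise_sd must be non-negative")
  if (illumination_drift_sd < 0) {
    stop("illumination_drift_sd must be non-negative")
  }
  if (is.null(density_by_genotype)) {
    density_by_genotype <- stats::setNames(
      seq(0.010, 0.014, length.out = 32), paste0("ZL", 1:32))
  }
  if (is.null(zoom_schedule)) zoom_schedule <- rep(1L, n_days)
  zoom_schedule <- as.integer(zoom_schedule)
  if (length(zoom_schedule) != n_days) {
    stop("zoom_schedule must supply one zoom level per imaging day")
  }
  if (!all(zoom_schedule %in% c(1L, 2L))) {
    stop("zoom levels must be 1 or 2")
  }
  cfg <- list(
    seed = as.integer(seed), n_days = as.integer(n_days),
    band_count = as.integer(band_count),
    wavelength_range_nm = as.numeric(wavelength_range_nm),
    genotype_variance = genotype_variance, row_variance = row_variance,
    error_variance = error_variance,
    density_by_genotype = density_by_genotype,
    biomass_noise_sd = biomass_noise_sd,
    illumination_drift_sd = illumination_drift_sd,
    zoom_schedule = zoom_schedule,
    canvas = as.integer(canvas), hyper_canvas = as.integer(hyper_canvas),
    height_max_px = height_max_px, width_max_px = width_max_px,
    emergence_px = emergence_px,
    plant_red = plant_red, background_red = background_red
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Band-centre wavelengths of a configuration's uniform spectral grid
#' @param config A [synth_config()] object.
#' @return Numeric vector of `band_count` ascending wavelengths (nm).
#' @export
config_wavelengths <- function(config) {
  seq(config$wavelength_range_nm[1], config$wavelength_range_nm[2],
      length.out = config$band_count)
}

#' Campaign-style zoom schedule
#'
#' Reproduces the acquisition campaign's zoom history on the synthetic day
#' axis: zoom level 1 throughout, except a one-day zoom reduction on day 18
#' (a system error applied the reduced zoom for a single day) and the final
#' days from `final_from` onward at zoom 2, when the plants outgrew the
#' zoom-1 frame.
#'
#' @param n_days Number of imaging days.
#' @param error_day Day index of the isolated zoom-2 day (default 18).
#' @param final_from First day of the terminal zoom-2 stretch (default 25).
#' @return Integer vector of zoom levels, length `n_days`.
#' @export
zoom_schedule_campaign <- function(n_days = 29L, error_day = 18L,
                                   final_from = 25L) {
  z <- rep(1L, n_days)
  if (error_day <= n_days) z[error_day] <- 2L
  if (final_from <= n_days) z[final_from:n_days] <- 2L
  z
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    paste0("<synth_config> seed %d, %d days, %d bands (%g-%g nm), ",
           "canvas %dx%d, variances g/r/e = %g/%g/%g\n"),
    x$seed, x$n_days, x$band_count, x$wavelength_range_nm[1],
    x$wavelength_range_nm[2], x$canvas[1], x$canvas[2],
    x$genotype_variance, x$row_variance, x$error_variance))
  invisible(x)
}
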