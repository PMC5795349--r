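# Synthetic phantom-plant generator. Every output is a pure function of
# (design, config); per-image randomness is drawn from seeds derived from
# the master seed and the pot/day/view tags, so renders are reproducible
# individually and in any order.

# Tags for the derived-seed stream (arbitrary but fixed).
.TAG <- list(panel_geno = 1L, panel_row = 2L, panel_eps = 3L,
             biomass = 5L, leaves = 11L, illum = 13L)

#' Simulate the growth-trait panel
#'
#' Draws true plant height and width for every occupied pot and imaging
#' day under the additive model `y = mu_t + alpha_row + gamma_genotype +
#' epsilon`: genotype effects are drawn once per genotype, row effects once
#' per greenhouse row, and the error term independently per plant and day.
#' The day trend `mu_t` is logistic (sigmoid growth), so plants emerge a
#' few days after sowing and approach the configured asymptote.
#'
#' @param design An [generate_design()] table.
#' @param config A [synth_config()]; `genotype_variance`, `row_variance`
#'   and `error_variance` set the component magnitudes (px^2) and `seed`
#'   fixes all draws.
#' @return Data frame with one row per plant x day: `pot_id`, `genotype`,
#'   `row`, `replicate`, `day`, `height_px`, `width_px` (continuous,
#'   truncated at zero).
#' @export
simulate_trait_panel <- function(design, config = synth_config()) {
  stopifnot(inherits(design, "experiment_design"))
  if (any(c(config$genotype_variance, config$row_variance,
            config$error_variance) < 0)) {
    stop("variance components must be non-negative")
  }
  plants <- design[!design$is_empty, , drop = FALSE]
  genos <- sort(unique(plants$genotype))
  n_g <- length(genos); n_r <- max(design$row)
  n_p <- nrow(plants); n_d <- config$n_days

  gamma <- with_local_seed(derive_seed(config$seed, .TAG$panel_geno), {
    matrix(stats::rnorm(n_g * 2, 0, sqrt(config$genotype_variance)),
           n_g, 2, dimnames = list(genos, c("height", "width")))
  })
  alpha <- with_local_seed(derive_seed(config$seed, .TAG$panel_row), {
    matrix(stats::rnorm(n_r * 2, 0, sqrt(config$row_variance)),
           n_r, 2)
  })
  eps <- with_local_seed(derive_seed(config$seed, .TAG$panel_eps), {
    array(stats::rnorm(n_p * n_d * 2, 0, sqrt(config$error_variance)),
          c(n_p, n_d, 2))
  })

  day <- rep(seq_len(n_d), each = n_p)
  pid <- rep(seq_len(n_p), times = n_d)
  mu_h <- config$height_max_px / (1 + exp(-(day - 15) / 3))
  mu_w <- config$width_max_px / (1 + exp(-(day - 15) / 3.5))
  g_idx <- match(plants$genotype, genos)
  h <- mu_h + alpha[plants$row[pid], 1] + gamma[g_idx[pid], 1] +
    eps[cbind(pid, day, 1L)]
  w <- mu_w + alpha[plants$row[pid], 2] + gamma[g_idx[pid], 2] +
    eps[cbind(pid, day, 2L)]
  data.frame(
    pot_id = plants$pot_id[pid], genotype = plants$genotype[pid],
    row = plants$row[pid], replicate = plants$replicate[pid],
    day = day, height_px = pmax(h, 0), width_px = pmax(w, 0),
    stringsAsFactors = FALSE
  )
}

# Rasterize the phantom: an axis-aligned stem rectangle plus elliptical
# leaves and a 2-px midrib spanning the full width, all clipped to the
# H x W bounding box, so the truth bounding box is analytic (height = H,
# width = W exactly). Returns plant/stem/leaf masks.
phantom_masks <- function(H, W, canvas, view, seed) {
  h <- canvas[1]; w <- canvas[2]
  empty <- matrix(FALSE, h, w)
  out <- list(plant = empty, stem = empty, leaf = empty,
              height_px = 0L, width_px = 0L, area_px = 0L)
  H <- as.integer(round(H)); W <- as.integer(round(W))
  if (H < 1L) return(out)
  W <- max(W, 3L)
  cx <- w %/% 2L
  W <- min(W, 2L * min(cx - 1L, w - cx) + 1L)
  half_l <- (W - 1L) %/% 2L; half_r <- W - 1L - half_l
  c0 <- cx - half_l; c1 <- cx + half_r

  if (view == "top") {
    # Viewed from above: a plus-shaped leaf cross spanning W in both axes,
    # with the stem visible as a 3 x 3 centre block.
    r_mid <- h %/% 2L
    H <- W  # y-extent of the top-view silhouette
    r0 <- r_mid - half_l; r1 <- r_mid + half_r
    leaf <- empty
    leaf[max(r_mid - 1L, 1L):min(r_mid + 1L, h), c0:c1] <- TRUE
    leaf[r0:r1, max(cx - 1L, 1L):min(cx + 1L, w)] <- TRUE
    stem <- empty
    stem[(r_mid - 1L):(r_mid + 1L), (cx - 1L):(cx + 1L)] <- TRUE
    leaf <- leaf & !stem
  } else {
    r0 <- h - 10L
    H <- min(H, r0)
    top <- r0 - H + 1L
    stem <- empty
    stem[top:r0, (cx - 1L):(cx + 1L)] <- TRUE
    leaf <- empty
    # midrib: guarantees the bounding-box width equals W
    r_m <- r0 - as.integer(floor(0.6 * H))
    r_m <- min(max(r_m, top), r0 - 1L)
    leaf[r_m:(r_m + 1L), c0:c1] <- TRUE
    # elliptical leaves at fixed relative heights, seeded orientations
    n_leaf <- 2L + H %/% 80L
    pars <- with_local_seed(seed, {
      list(th = stats::runif(n_leaf, -0.6, 0.6),
           side = sample(c(-1, 1), n_leaf, replace = TRUE))
    })
    for (k in seq_len(n_leaf)) {
      rc <- r0 - floor(H * (0.30 + 0.18 * k))
      a <- max(4, min(half_l, 6 + 0.25 * W))
      b <- max(2, a / 4)
      rows <- max(top, rc - 15L):min(r0, rc + 15L)
      cols <- c0:c1
      yy <- outer(rows - rc, rep(1, length(cols)))
      xx <- outer(rep(1, length(rows)), cols - cx)
      th <- pars$th[k]
      xr <- xx * cos(th) + yy * sin(th)
      yr <- -xx * sin(th) + yy * cos(th)
      # shift the ellipse centre off the stem to one side
      xs <- xr - pars$side[k] * a * 0.45
      inside <- (xs / a)^2 + (yr / b)^2 <= 1
      leaf[rows, cols] <- leaf[rows, cols] | inside
    }
    leaf <- leaf & !stem
    # clip to the bounding box
    keep <- empty; keep[top:r0, c0:c1] <- TRUE
    leaf <- leaf & keep
  }
  plant <- stem | leaf
  bb <- which(plant, arr.ind = TRUE)
  list(plant = plant, stem = stem & plant, leaf = leaf,
       height_px = diff(range(bb[, 1])) + 1L,
       width_px = diff(range(bb[, 2])) + 1L,
       area_px = sum(plant))
}

# Look up one pot and its trait values for a day; NULL trait row for empty
# pots.
pot_state <- function(design, plant, day, config, panel) {
  pot <- design[design$pot_id == plant, , drop = FALSE]
  if (nrow(pot) != 1L) stop("unknown pot id: ", plant)
  if (day < 1L || day > config$n_days) stop("day outside imaging campaign")
  if (pot$is_empty) return(list(pot = pot, traits = NULL))
  if (is.null(panel)) panel <- simulate_trait_panel(design, config)
  tr <- panel[panel$pot_id == plant & panel$day == day, , drop = FALSE]
  list(pot = pot, traits = tr)
}

#' Render a synthetic RGB scene
#'
#' Draws the phantom plant (vertical stem rectangle plus elliptical
#' leaves) for one pot, day and view on a uniform gray background. Plant
#' pixels are coloured so that their green index `2G/(R+B)` exceeds the
#' segmentation threshold 1.15 and background pixels sit at exactly 1.0,
#' making the generator an exact oracle for the RGB segmenter. Empty pots
#' and days before emergence render as pure background with an all-false
#' truth mask.
#'
#' @param design An [generate_design()] table.
#' @param plant Pot id (e.g. `"017"`).
#' @param day Imaging-day index.
#' @param view `"side0"`, `"side90"` or `"top"`.
#' @param config A [synth_config()].
#' @param panel Optional precomputed [simulate_trait_panel()] table (saves
#'   recomputation when rendering many scenes).
#' @return List with `image` (a [raster_image()]) and `truth` (plant,
#'   stem and leaf masks plus `height_px`, `width_px`, `area_px`).
#' @export
render_rgb_scene <- function(design, plant, day, view = "side0",
                             config = synth_config(), panel = NULL) {
  st <- pot_state(design, plant, day, config, panel)
  cv <- config$canvas
  msk <- if (is.null(st$traits) ||
             st$traits$height_px < config$emergence_px) {
    phantom_masks(0, 0, cv, view, 0L)
  } else {
    phantom_masks(st$traits$height_px, st$traits$width_px, cv, view,
                  derive_seed(config$seed, .TAG$leaves,
                              round(st$traits$height_px),
                              round(st$traits$width_px)))
  }
  img <- array(0, c(cv[1], cv[2], 3))
  img[, , 1] <- 100; img[, , 2] <- 100; img[, , 3] <- 100
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[msk$leaf] <- c(60, 120, 40)[ch]
    plane[msk$stem] <- c(80, 130, 50)[ch]
    img[, , ch] <- plane
  }
  zoom <- config$zoom_schedule[day]
  list(image = raster_image(img, view = view, day = day, zoom = zoom),
       truth = msk)
}

#' Render a synthetic fluorescence image
#'
#' Same phantom geometry as [render_rgb_scene()], but imaged as a
#' fluorescence camera would see it: nearly all signal in the red channel,
#' plant pixels above the red-channel segmentation threshold of 70 and
#' background pixels below it.
#'
#' @inheritParams render_rgb_scene
#' @return List with `image` (a [raster_image()]) and `truth` masks.
#' @export
render_fluorescence_image <- function(design, plant, day, view = "side0",
                                      config = synth_config(),
                                      panel = NULL) {
  st <- pot_state(design, plant, day, config, panel)
  cv <- config$canvas
  msk <- if (is.null(st$traits) ||
             st$traits$height_px < config$emergence_px) {
    phantom_masks(0, 0, cv, view, 0L)
  } else {
    phantom_masks(st$traits$height_px, st$traits$width_px, cv, view,
                  derive_seed(config$seed, .TAG$leaves,
                              round(st$traits$height_px),
                              round(st$traits$width_px)))
  }
  img <- array(0, c(cv[1], cv[2], 3))
  red <- matrix(config$background_red, cv[1], cv[2])
  red[msk$plant] <- config$plant_red
  img[, , 1] <- red
  img[, , 2] <- 2; img[, , 3] <- 1
  zoom <- config$zoom_schedule[day]
  list(image = raster_image(img, view = view, day = day, zoom = zoom),
       truth = msk)
}

# Reference reflectance templates on an arbitrary wavelength grid.
# Leaf: classic green-vegetation curve (strong red-edge rise, water
# absorption dips) giving NDVI ~ 0.57. Stem: elevated plateau around
# 1056 nm relative to 1151 nm (ratio ~ 1.4). Background: spectrally flat,
# NDVI exactly 0 and ratio 1.
spectral_templates <- function(wavelengths) {
  leaf_pts <- cbind(
    c(546, 650, 705, 750, 1000, 1056, 1100, 1151, 1300, 1450, 1700),
    c(0.10, 0.08, 0.15, 0.55, 0.50, 0.45, 0.445, 0.44, 0.30, 0.12, 0.18))
  stem_pts <- cbind(
    c(546, 650, 705, 750, 1000, 1056, 1100, 1151, 1300, 1450, 1700),
    c(0.12, 0.10, 0.20, 0.50, 0.55, 0.56, 0.48, 0.40, 0.28, 0.15, 0.20))
  list(
    background = rep(0.25, length(wavelengths)),
    leaf = stats::approx(leaf_pts[, 1], leaf_pts[, 2], wavelengths,
                         rule = 2)$y,
    stem = stats::approx(stem_pts[, 1], stem_pts[, 2], wavelengths,
                         rule = 2)$y
  )
}

#' Render a synthetic hyperspectral cube
#'
#' Emits one grayscale plane per configured band on the uniform wavelength
#' grid. Leaf pixels carry a green-vegetation template spectrum (NDVI above
#' the 0.25 plant threshold), stem pixels a template whose
#' 1056 nm / 1151 nm ratio exceeds the 1.2 stem threshold, and background
#' pixels a flat spectrum (NDVI 0). The whole image is multiplied by a
#' per-image illumination factor drawn from a lognormal with log-sd
#' `illumination_drift_sd` (clamped to `[0.6, 1.4]` so 8-bit quantization
#' never clips); band ratios are invariant to this global factor, which is
#' exactly what the background-based normalization is meant to remove.
#' The phantom geometry is the RGB phantom scaled to `hyper_canvas`.
#'
#' @inheritParams render_rgb_scene
#' @param view Side view only (`"side0"` or `"side90"`).
#' @return List with `cube` (a [hyper_cube()]) and `truth` masks at the
#'   hyperspectral canvas resolution.
#' @export
render_hypercube <- function(design, plant, day, view = "side0",
                             config = synth_config(), panel = NULL) {
  if (config$band_count < 2L) stop("band_count must be at least 2")
  st <- pot_state(design, plant, day, config, panel)
  cv <- config$hyper_canvas
  scl <- cv[1] / config$canvas[1]
  msk <- if (is.null(st$traits) ||
             st$traits$height_px < config$emergence_px) {
    phantom_masks(0, 0, cv, view, 0L)
  } else {
    phantom_masks(st$traits$height_px * scl, st$traits$width_px * scl,
                  cv, view,
                  derive_seed(config$seed, .TAG$leaves,
                              round(st$traits$height_px * scl),
                              round(st$traits$width_px * scl)))
  }
  wl <- config_wavelengths(config)
  tpl <- spectral_templates(wl)
  illum <- if (config$illumination_drift_sd == 0) 1 else {
    with_local_seed(
      derive_seed(config$seed, .TAG$illum,
                  as.integer(st$pot$row) * 100L + as.integer(st$pot$col),
                  day, match(view, c("side0", "side90", "top"))),
      min(max(exp(stats::rnorm(1, 0, config$illumination_drift_sd)),
              0.6), 1.4))
  }
  planes <- array(0, c(cv[1], cv[2], config$band_count))
  for (b in seq_len(config$band_count)) {
    pl <- matrix(tpl$background[b], cv[1], cv[2])
    pl[msk$leaf] <- tpl$leaf[b]
    pl[msk$stem] <- tpl$stem[b]
    planes[, , b] <- quantize8(pl * illum)
  }
  list(cube = hyper_cube(planes, wl), truth = msk)
}

#' Simulate ground-truth fresh biomass from plant area
#'
#' Fresh biomass is genotype density times zoom-adjusted plant area plus
#' optional measurement noise. Because tissue density differs between
#' genotypes (different leaf-to-stem ratios), any predictor that sees only
#' pixel area inherits a systematic, genotype-confounded error -- the
#' phenomenon the biomass error decomposition quantifies.
#'
#' @param areas Data frame with columns `pot_id`, `genotype`, and
#'   `area_adj` (zoom-1-equivalent plant pixels, typically the sum of the
#'   two side views on the final imaging day).
#' @param config A [synth_config()]; supplies `density_by_genotype`
#'   (g per adjusted pixel), `biomass_noise_sd` and the seed.
#' @return Data frame `pot_id`, `genotype`, `fresh_biomass_g`.
#' @export
simulate_biomass_truth <- function(areas, config = synth_config()) {
  stopifnot(all(c("pot_id", "genotype", "area_adj") %in% names(areas)))
  dens <- config$density_by_genotype[areas$genotype]
  if (anyNA(dens)) {
    missing <- unique(areas$genotype[is.na(dens)])
    stop("no density configured for genotype(s): ",
         paste(missing, collapse = ", "))
  }
  noise <- if (config$biomass_noise_sd > 0) {
    with_local_seed(derive_seed(config$seed, .TAG$biomass),
                    stats::rnorm(nrow(areas), 0, config$biomass_noise_sd))
  } else rep(0, nrow(areas))
  data.frame(pot_id = areas$pot_id, genotype = areas$genotype,
             fresh_biomass_g = as.numeric(dens) * areas$area_adj + noise,
             stringsAsFactors = FALSE)
}

#' Assemble biomass model features directly from in-memory renders
#'
#' Convenience wrapper that renders the final-day (or chosen day) scenes
#' for every plant in `design`, runs the actual segmentation and geometry
#' extraction on them, and returns the six-feature table used by
#' [fit_biomass()], together with simulated ground-truth biomass. This is
#' the closed loop used for validation: features come out of the same
#' image-processing path a real dataset would take.
#'
#' @param design An [generate_design()] table (or a subset of its rows).
#' @param config A [synth_config()].
#' @param day Imaging day (default: final day).
#' @param panel Optional precomputed trait panel.
#' @return A `biomass_features` data frame (see [assemble_features()]).
#' @export
synthesize_features <- function(design, config = synth_config(),
                                day = config$n_days, panel = NULL) {
  if (is.null(panel)) panel <- simulate_trait_panel(design, config)
  plants <- design[!design$is_empty, , drop = FALSE]
  calib <- zoom_calibration(schedule = config$zoom_schedule)
  rows <- lapply(seq_len(nrow(plants)), function(i) {
    pid <- plants$pot_id[i]
    geo <- lapply(c("side0", "side90", "top"), function(v) {
      sc <- render_rgb_scene(design, pid, day, v, config, panel)
      mask <- segment_plant(sc$image)
      extract_geometry(mask, calib, day)
    })
    fl <- lapply(c("side0", "side90", "top"), function(v) {
      sc <- render_fluorescence_image(design, pid, day, v, config, panel)
      fluorescence_intensity(segment_fluorescence(sc$image), sc$image)
    })
    hy <- render_hypercube(design, pid, day, "side0", config, panel)
    pm <- segment_plant_ndvi(hy$cube)
    sl <- segment_stem(hy$cube, pm)
    agg <- function(f) if (is.na(f$n_pixels)) 0 else f$aggregate_intensity
    data.frame(
      pot_id = pid, genotype = plants$genotype[i],
      replicate = plants$replicate[i],
      side_pixels = sum(geo[[1]]$area_adj, geo[[2]]$area_adj, na.rm = TRUE),
      side_top_pixels = sum(geo[[1]]$area_adj, geo[[2]]$area_adj,
                            geo[[3]]$area_px, na.rm = TRUE),
      fluor_side = agg(fl[[1]]) + agg(fl[[2]]),
      fluor_side_top = agg(fl[[1]]) + agg(fl[[2]]) + agg(fl[[3]]),
      stem_pixels = sum(sl$stem), leaf_pixels = sum(sl$leaf),
      stringsAsFactors = FALSE
    )
  })
  feats <- do.call(rbind, rows)
  feats$area_adj <- feats$side_pixels
  bm <- simulate_biomass_truth(feats[, c("pot_id", "genotype", "area_adj")],
                               config)
  feats$fresh_biomass_g <- bm$fresh_biomass_g
  feats$area_adj <- NULL
  class(feats) <- c("biomass_features", "data.frame")
  feats
}
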