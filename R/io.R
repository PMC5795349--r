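# Dataset layout: root/Genotype_<g>/Plant_<pot>-<num>/<Camera>/Day_<dd>/
# with side0/side90/top.png for RGB and Fluorescence, and per-band
# grayscale PNGs (band_###_<nm>nm.png) directly under the day directory
# for Hyperspectral. Real deposits differ in naming details; the path
# parser is kept in one place (index_dataset) so other dialects can be
# plugged in.

.CAMERAS <- c("RGB", "Fluorescence", "Hyperspectral")

#' Write a synthetic experiment to disk in the released-dataset layout
#'
#' Renders and writes PNG imagery for every occupied pot in `design`
#' (nested `Genotype -> Plant -> Camera type -> Day`), together with
#' `design.csv`, the true trait panel (`truth_traits.csv`), ground-truth
#' biomass (`biomass.csv`, computed from the final written day), and a
#' plain pot-weight stub (`pot_weights.csv`). Hyperspectral cubes are
#' large (one file per band), so they are written only for
#' `hyper_days`/`hyper_pots` (defaults: final day, all pots).
#'
#' @param out Output root directory.
#' @param config A [synth_config()].
#' @param design An [generate_design()] table; defaults to seed-0 design.
#' @param days Imaging days to write (default: all `config$n_days`).
#' @param cameras Subset of `c("RGB", "Fluorescence", "Hyperspectral")`.
#' @param hyper_days,hyper_pots Days and pot ids for which hyperspectral
#'   cubes are written.
#' @return The root path, invisibly.
#' @export
simulate_experiment <- function(out, config = synth_config(),
                                design = generate_design(config$seed),
                                days = seq_len(config$n_days),
                                cameras = .CAMERAS,
                                hyper_days = max(days),
                                hyper_pots = NULL) {
  stopifnot(all(cameras %in% .CAMERAS), all(days <= config$n_days))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_trait_panel(design, config)
  utils::write.csv(as.data.frame(design),
                   file.path(out, "design.csv"), row.names = FALSE)
  utils::write.csv(panel, file.path(out, "truth_traits.csv"),
                   row.names = FALSE)
  plants <- design[!design$is_empty, , drop = FALSE]
  if (is.null(hyper_pots)) hyper_pots <- plants$pot_id
  views <- c("side0", "side90", "top")
  areas <- numeric(nrow(plants))
  final_day <- max(days)
  for (i in seq_len(nrow(plants))) {
    pid <- plants$pot_id[i]
    pdir <- file.path(out, paste0("Genotype_", plants$genotype[i]),
                      sprintf("Plant_%s-%s", pid,
                              sub("^ZL", "", plants$genotype[i])))
    for (d in days) {
      for (v in views) {
        if ("RGB" %in% cameras) {
          sc <- render_rgb_scene(design, pid, d, v, config, panel)
          dd <- file.path(pdir, "RGB", sprintf("Day_%02d", d))
          dir.create(dd, recursive = TRUE, showWarnings = FALSE)
          write_raster(sc$image, file.path(dd, paste0(v, ".png")))
          if (d == final_day && v %in% c("side0", "side90")) {
            zoom <- config$zoom_schedule[d]
            calib <- zoom_calibration(schedule = config$zoom_schedule)
            adj <- (mm_per_pixel(calib, zoom) /
                      calib$mm_per_pixel_zoom1)^2
            areas[i] <- areas[i] + sc$truth$area_px * adj
          }
        }
        if ("Fluorescence" %in% cameras) {
          sc <- render_fluorescence_image(design, pid, d, v, config,
                                          panel)
          dd <- file.path(pdir, "Fluorescence", sprintf("Day_%02d", d))
          dir.create(dd, recursive = TRUE, showWarnings = FALSE)
          write_raster(sc$image, file.path(dd, paste0(v, ".png")))
        }
      }
      if ("Hyperspectral" %in% cameras && d %in% hyper_days &&
          pid %in% hyper_pots) {
        hy <- render_hypercube(design, pid, d, "side0", config, panel)
        write_cube(hy$cube,
                   file.path(pdir, "Hyperspectral",
                             sprintf("Day_%02d", d)))
      }
    }
  }
  if ("RGB" %in% cameras) {
    bm <- simulate_biomass_truth(
      data.frame(pot_id = plants$pot_id, genotype = plants$genotype,
                 area_adj = areas, stringsAsFactors = FALSE),
      config)
    utils::write.csv(bm, file.path(out, "biomass.csv"),
                     row.names = FALSE)
  }
  # plain stub: daily pot weights are released with the real data but not
  # modelled here
  utils::write.csv(
    data.frame(pot_id = plants$pot_id, day = NA_integer_,
               weight_g = NA_real_)[0, ],
    file.path(out, "pot_weights.csv"), row.names = FALSE)
  invisible(out)
}

#' Index a dataset directory tree
#'
#' Walks the `Genotype -> Plant -> Camera type -> Day` layout and returns
#' one record per image file: genotype, pot id, camera, day, view (RGB
#' and fluorescence) or wavelength (hyperspectral band files), and path.
#' Unknown camera-type directories are skipped with a warning.
#'
#' @param root Dataset root.
#' @return Data frame of class `dataset_index`.
#' @export
index_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  gdirs <- list.dirs(root, recursive = FALSE)
  gdirs <- gdirs[grepl("^Genotype_", basename(gdirs))]
  if (length(gdirs) == 0L) stop("no Genotype_* directories under ", root)
  recs <- list()
  for (g in gdirs) {
    genotype <- sub("^Genotype_", "", basename(g))
    for (p in list.dirs(g, recursive = FALSE)) {
      if (!grepl("^Plant_", basename(p))) next
      pot_id <- sub("^Plant_([^-]+)-.*$", "\\1", basename(p))
      for (cam in list.dirs(p, recursive = FALSE)) {
        cam_name <- basename(cam)
        if (!cam_name %in% .CAMERAS) {
          warning("skipping unknown camera type: ", cam_name)
          next
        }
        for (dd in list.dirs(cam, recursive = FALSE)) {
          day <- suppressWarnings(
            as.integer(sub("^Day_", "", basename(dd))))
          if (is.na(day)) next
          files <- list.files(dd, pattern = "\\.png$",
                              full.names = TRUE)
          if (length(files) == 0L) next
          if (cam_name == "Hyperspectral") {
            wl <- as.numeric(sub("^band_\\d+_(.*)nm\\.png$", "\\1",
                                 basename(files)))
            recs[[length(recs) + 1L]] <- data.frame(
              genotype = genotype, pot_id = pot_id, camera = cam_name,
              day = day, view = NA_character_, wavelength = wl,
              path = files, stringsAsFactors = FALSE)
          } else {
            view <- sub("\\.png$", "", basename(files))
            keep <- view %in% c("side0", "side90", "top")
            recs[[length(recs) + 1L]] <- data.frame(
              genotype = genotype, pot_id = pot_id, camera = cam_name,
              day = day, view = view[keep], wavelength = NA_real_,
              path = files[keep], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  idx <- do.call(rbind, recs)
  if (is.null(idx) || nrow(idx) == 0L) stop("no images found under ", root)
  idx <- idx[order(idx$pot_id, idx$camera, idx$day, idx$view), ]
  rownames(idx) <- NULL
  class(idx) <- c("dataset_index", "data.frame")
  idx
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %d records, %d plants, cameras: %s\n",
              nrow(x), length(unique(x$pot_id)),
              paste(sort(unique(x$camera)), collapse = ", ")))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects the segmentation thresholds, zoom calibration, optional
#' exclusion/ROI rectangles, and smoothing/seed settings used by
#' [run_pipeline()]. Defaults are the published processing constants:
#' green index 1.15, NDVI 0.25, stem ratio 1.2, fluorescence red
#' threshold 70, 0.746 / 1.507 mm per pixel.
#'
#' @param green_threshold,ndvi_threshold,stem_threshold,fluor_threshold
#'   Segmentation cutoffs (all strict comparisons).
#' @param calib A [zoom_calibration()].
#' @param exclusions RGB exclusion rectangles.
#' @param roi Fluorescence region-of-interest rectangle (or `NULL` for
#'   the full canvas).
#' @param bandwidth Heritability smoothing bandwidth (days).
#' @param falsecolor Write PCA false-colour PNGs for each cube?
#' @param seed Seed for stochastic model fits.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(green_threshold = 1.15,
                            ndvi_threshold = 0.25,
                            stem_threshold = 1.2,
                            fluor_threshold = 70,
                            calib = zoom_calibration(),
                            exclusions = list(), roi = NULL,
                            bandwidth = 2, falsecolor = FALSE,
                            seed = 1L) {
  if (any(c(green_threshold, ndvi_threshold, stem_threshold,
            fluor_threshold) <= 0)) {
    stop("thresholds must be positive")
  }
  structure(list(green_threshold = green_threshold,
                 ndvi_threshold = ndvi_threshold,
                 stem_threshold = stem_threshold,
                 fluor_threshold = fluor_threshold,
                 calib = calib, exclusions = exclusions, roi = roi,
                 bandwidth = bandwidth, falsecolor = falsecolor,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [pipeline_config()]; the zoom
#' schedule may be given as `zoom_schedule: [1, 1, 2, ...]`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configuration needs the yaml package")
  }
  y <- yaml::read_yaml(path)
  calib <- zoom_calibration(
    mm_per_pixel_zoom1 = y$mm_per_pixel_zoom1 %||% 0.746,
    mm_per_pixel_zoom2 = y$mm_per_pixel_zoom2 %||% 1.507,
    schedule = unlist(y$zoom_schedule %||% rep(1L, 29L)))
  pipeline_config(
    green_threshold = y$green_threshold %||% 1.15,
    ndvi_threshold = y$ndvi_threshold %||% 0.25,
    stem_threshold = y$stem_threshold %||% 1.2,
    fluor_threshold = y$fluor_threshold %||% 70,
    calib = calib,
    bandwidth = y$bandwidth %||% 2,
    falsecolor = isTRUE(y$falsecolor),
    seed = y$seed %||% 1L)
}

#' Run the full extraction-to-analysis pipeline on a dataset
#'
#' Indexes the dataset, extracts RGB geometry traits, fluorescence
#' intensities, and hyperspectral stem/leaf counts and tissue spectra,
#' then (when the design and ground-truth biomass files are present)
#' computes per-day heritability series and the biomass models with their
#' genotype error fractions. Each stage's completion state is recorded in
#' `MANIFEST.txt`; on a stage failure the partial outputs are retained
#' and the error re-raised.
#'
#' @param root Dataset root (as written by [simulate_experiment()]).
#' @param out Output directory for `traits.csv`, `fluor.csv`,
#'   `spectra.csv`, `hyper_counts.csv`, `h2.csv`, `biomass.json`, and
#'   optional false-colour PNGs.
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(root, out, config = pipeline_config()) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out, "MANIFEST.txt")
  status <- character()
  note <- function(stage, state) {
    status <<- c(status, sprintf("%s: %s", stage, state))
    writeLines(status, manifest)
  }
  run_stage <- function(stage, expr) {
    tryCatch({
      res <- force(expr)
      note(stage, "ok")
      res
    }, error = function(e) {
      note(stage, paste("failed -", conditionMessage(e)))
      stop(e)
    })
  }
  paths <- list()

  idx <- run_stage("index", index_dataset(root))
  days <- sort(unique(idx$day))
  if (max(days) > length(config$calib$schedule)) {
    stop("zoom schedule does not cover imaging day ", max(days))
  }
  message(sprintf("indexed %d records from %d plants over %d days",
                  nrow(idx), length(unique(idx$pot_id)), length(days)))

  traits <- run_stage("extract-rgb", {
    tr <- build_trait_timeseries(root, config$calib,
                                 config$green_threshold,
                                 config$exclusions)
    paths$traits <- file.path(out, "traits.csv")
    utils::write.csv(tr, paths$traits, row.names = FALSE, na = "")
    tr
  })

  fluor <- run_stage("extract-fluor", {
    fr <- idx[idx$camera == "Fluorescence", , drop = FALSE]
    tab <- do.call(rbind, lapply(seq_len(nrow(fr)), function(i) {
      img <- read_raster(fr$path[i], view = fr$view[i], day = fr$day[i])
      m <- segment_fluorescence(img, config$roi, config$fluor_threshold)
      fi <- fluorescence_intensity(m, img)
      data.frame(pot_id = fr$pot_id[i], genotype = fr$genotype[i],
                 day = fr$day[i], view = fr$view[i],
                 aggregate_intensity = fi$aggregate_intensity,
                 mean_intensity = fi$mean_intensity,
                 n_pixels = fi$n_pixels, stringsAsFactors = FALSE)
    }))
    paths$fluor <- file.path(out, "fluor.csv")
    if (!is.null(tab)) {
      utils::write.csv(tab, paths$fluor, row.names = FALSE, na = "")
    }
    tab
  })

  hyper <- run_stage("extract-hyper", {
    hr <- unique(idx[idx$camera == "Hyperspectral",
                     c("pot_id", "genotype", "day", "path")])
    if (nrow(hr) == 0L) NULL else {
      day_dirs <- unique(dirname(hr$path))
      counts <- list(); spectra <- list()
      for (dd in day_dirs) {
        rec <- hr[dirname(hr$path) == dd, ][1, ]
        cube <- read_cube(dd)
        pm <- segment_plant_ndvi(cube, config$ndvi_threshold)
        if (is_na_mask(pm)) {
          counts[[dd]] <- data.frame(
            pot_id = rec$pot_id, genotype = rec$genotype, day = rec$day,
            stem_pixels = NA_real_, leaf_pixels = NA_real_,
            stringsAsFactors = FALSE)
          next
        }
        sl <- segment_stem(cube, pm, config$stem_threshold)
        norm <- normalize_cube(cube, pm)
        counts[[dd]] <- data.frame(
          pot_id = rec$pot_id, genotype = rec$genotype, day = rec$day,
          stem_pixels = sum(sl$stem), leaf_pixels = sum(sl$leaf),
          stringsAsFactors = FALSE)
        sp <- rbind(
          if (any(sl$stem)) mean_spectrum(norm, sl$stem, "stem"),
          if (any(sl$leaf)) mean_spectrum(norm, sl$leaf, "leaf"))
        sp$pot_id <- rec$pot_id; sp$day <- rec$day
        spectra[[dd]] <- sp
        if (isTRUE(config$falsecolor)) {
          fc <- pca_false_color(norm, pm)
          write_raster(fc, file.path(
            out, sprintf("falsecolor_%s_day%02d.png", rec$pot_id,
                         rec$day)))
        }
      }
      paths$hyper_counts <- file.path(out, "hyper_counts.csv")
      utils::write.csv(do.call(rbind, counts), paths$hyper_counts,
                       row.names = FALSE, na = "")
      if (length(spectra) > 0L) {
        paths$spectra <- file.path(out, "spectra.csv")
        utils::write.csv(do.call(rbind, spectra), paths$spectra,
                         row.names = FALSE, na = "")
      }
      do.call(rbind, counts)
    }
  })

  design_path <- file.path(root, "design.csv")
  design <- NULL
  if (file.exists(design_path)) {
    design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
    design$pot_id <- sprintf("%03d", as.integer(design$pot_id))
    class(design) <- c("experiment_design", "data.frame")
  }

  run_stage("heritability", {
    if (is.null(design)) "skipped (no design.csv)" else {
      obs <- traits
      m <- match(obs$pot_id, design$pot_id)
      obs$row <- design$row[m]
      obs$replicate <- design$replicate[m]
      code_map <- list(PH0 = c("side0", "height_mm"),
                       PH90 = c("side90", "height_mm"),
                       PW0 = c("side0", "width_mm"),
                       PW90 = c("side90", "width_mm"),
                       PA0 = c("side0", "area_adj"),
                       PA90 = c("side90", "area_adj"))
      h2 <- list()
      for (code in names(code_map)) {
        sel <- obs[obs$view == code_map[[code]][1] &
                     obs$trait == code_map[[code]][2], , drop = FALSE]
        if (nrow(sel) == 0L) next
        ser <- heritability_series(sel, config$bandwidth)
        ser$trait <- code
        h2[[code]] <- ser
      }
      if (length(h2) > 0L) {
        paths$h2 <- file.path(out, "h2.csv")
        utils::write.csv(do.call(rbind, h2), paths$h2,
                         row.names = FALSE, na = "")
      }
      "ok"
    }
  })

  run_stage("biomass", {
    bm_path <- file.path(root, "biomass.csv")
    if (!file.exists(bm_path) || is.null(design) || is.null(hyper) ||
        is.null(fluor)) {
      "skipped (needs biomass.csv, design.csv, hyper and fluor data)"
    } else {
      bm <- utils::read.csv(bm_path, stringsAsFactors = FALSE)
      bm$pot_id <- sprintf("%03d", as.integer(bm$pot_id))
      feats <- assemble_features(traits, fluor, hyper, bm, design)
      fits <- list()
      for (mth in c("univariate_linear", "multivariate_linear")) {
        ft <- tryCatch(fit_biomass(feats, mth, seed = config$seed),
                       error = function(e) NULL)
        if (is.null(ft)) next
        frac <- tryCatch(genotype_error_fraction(ft, design),
                         error = function(e) NA_real_)
        fits[[mth]] <- list(method = mth, r = ft$r,
                            genotype_error_fraction = frac,
                            n = length(ft$measured))
      }
      paths$biomass <- file.path(out, "biomass.json")
      jsonlite::write_json(fits, paths$biomass, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      "ok"
    }
  })

  invisible(paths)
}
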