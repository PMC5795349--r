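#' Green index of an RGB image
#'
#' Computes the per-pixel colour-ratio statistic `2G / (R + B)` used to
#' separate green vegetation from background. Degenerate pixels are
#' defined explicitly: where `R + B = 0` and `G > 0` the index is `Inf`
#' (saturated green), and where all channels are zero it is 0.
#'
#' @param image A [raster_image()] or a `h x w x 3` array of 0--255
#'   intensities.
#' @return Numeric matrix of index values, same dimensions as the image.
#' @examples
#' px <- array(c(60, 120, 40), c(1, 1, 3))  # R=60, G=120, B=40
#' green_index(px)  # 240 / 100 = 2.4
#' @export
green_index <- function(image) {
  x <- unclass(image)
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  denom <- x[, , 1] + x[, , 3]
  g2 <- 2 * x[, , 2]
  idx <- ifelse(denom == 0, ifelse(g2 > 0, Inf, 0), g2 / denom)
  matrix(idx, dim(x)[1], dim(x)[2])
}

#' Segment plant pixels from an RGB image
#'
#' Marks as plant every pixel whose green index is strictly greater than
#' `threshold` and which lies outside all exclusion rectangles (used on
#' real images to suppress false positives from reflective chamber
#' columns). When no pixel passes, the mask is flagged `NA` -- the
#' convention for pre-emergence days.
#'
#' @param image A [raster_image()] or `h x w x 3` array.
#' @param threshold Green-index cutoff; strictly-greater comparison
#'   (default 1.15).
#' @param exclusions List of rectangles `c(rmin, rmax, cmin, cmax)`
#'   (1-based, inclusive) whose pixels are never counted as plant.
#' @return Logical plant mask with attribute `is_na` (`TRUE` iff no plant
#'   pixel was found).
#' @seealso [extract_geometry()], [is_na_mask()]
#' @export
segment_plant <- function(image, threshold = 1.15, exclusions = list()) {
  idx <- green_index(image)
  mask <- idx > threshold
  for (rect in exclusions) {
    rect <- check_rect(rect, dim(mask), "exclusion rectangle")
    mask[rect[1]:rect[2], rect[3]:rect[4]] <- FALSE
  }
  attr(mask, "is_na") <- !any(mask)
  mask
}

#' Is a plant mask empty?
#' @param mask A mask from [segment_plant()] or any logical matrix.
#' @return `TRUE` when the mask contains no plant pixel.
#' @export
is_na_mask <- function(mask) {
  flag <- attr(mask, "is_na")
  if (!is.null(flag)) flag else !any(mask)
}

#' Pixel-to-millimetre zoom calibration
#'
#' The imaging platform's side-view cameras operate at two zoom levels:
#' at zoom 1 each pixel spans 0.746 mm at the pot distance, at zoom 2
#' 1.507 mm (an approximate two-fold change used late in the campaign to
#' keep tall plants in frame). Areas are additionally expressed as
#' "adjusted pixels": the zoom-1-equivalent pixel count,
#' `area_px * (mm_per_pixel(zoom) / mm_per_pixel(zoom 1))^2`, so counts
#' taken at different zooms are commensurable.
#'
#' @param mm_per_pixel_zoom1,mm_per_pixel_zoom2 Calibration factors (mm).
#' @param schedule Integer vector mapping imaging day to zoom level.
#' @return List of class `zoom_calibration`.
#' @export
zoom_calibration <- function(mm_per_pixel_zoom1 = 0.746,
                             mm_per_pixel_zoom2 = 1.507,
                             schedule = rep(1L, 29L)) {
  if (mm_per_pixel_zoom1 <= 0 || mm_per_pixel_zoom2 <= 0) {
    stop("calibration factors must be positive")
  }
  if (!all(schedule %in% c(1L, 2L))) stop("zoom levels must be 1 or 2")
  structure(list(mm_per_pixel_zoom1 = mm_per_pixel_zoom1,
                 mm_per_pixel_zoom2 = mm_per_pixel_zoom2,
                 schedule = as.integer(schedule)),
            class = "zoom_calibration")
}

mm_per_pixel <- function(calib, zoom) {
  if (zoom == 1L) calib$mm_per_pixel_zoom1 else calib$mm_per_pixel_zoom2
}

#' Extract bounding-box geometry traits from a plant mask
#'
#' Height and width are the y- and x-extents (inclusive pixel counts) of
#' the axis-aligned minimum bounding box of the plant pixels; area is the
#' plant-pixel count. Millimetre traits use the zoom level scheduled for
#' `day`; `area_adj` is the zoom-1-equivalent pixel count. An empty
#' (`NA`) mask propagates `NA` to every field.
#'
#' @param mask Logical plant mask (see [segment_plant()]).
#' @param calib A [zoom_calibration()].
#' @param day Imaging day, used to look up the zoom level; alternatively
#'   pass `zoom` directly.
#' @param zoom Optional explicit zoom level overriding the schedule.
#' @return One-row data frame: `height_px`, `width_px`, `area_px`,
#'   `height_mm`, `width_mm`, `area_adj`, `area_mm2`, `zoom`.
#' @examples
#' m <- matrix(FALSE, 120, 40); m[10:109, 5:24] <- TRUE
#' extract_geometry(m, zoom_calibration(), day = 1)  # height 100, width 20
#' @export
extract_geometry <- function(mask, calib = zoom_calibration(), day = 1L,
                             zoom = NULL) {
  if (is.null(zoom)) {
    if (day < 1L || day > length(calib$schedule)) {
      stop("no zoom scheduled for day ", day)
    }
    zoom <- calib$schedule[day]
  }
  if (is_na_mask(mask)) {
    return(data.frame(height_px = NA_real_, width_px = NA_real_,
                      area_px = NA_real_, height_mm = NA_real_,
                      width_mm = NA_real_, area_adj = NA_real_,
                      area_mm2 = NA_real_, zoom = as.integer(zoom)))
  }
  bb <- which(mask, arr.ind = TRUE)
  h_px <- diff(range(bb[, 1])) + 1L
  w_px <- diff(range(bb[, 2])) + 1L
  a_px <- nrow(bb)
  mm <- mm_per_pixel(calib, zoom)
  data.frame(
    height_px = as.numeric(h_px), width_px = as.numeric(w_px),
    area_px = as.numeric(a_px),
    height_mm = h_px * mm, width_mm = w_px * mm,
    area_adj = a_px * (mm / calib$mm_per_pixel_zoom1)^2,
    area_mm2 = a_px * mm^2, zoom = as.integer(zoom)
  )
}

#' Build the per-day RGB trait table for a dataset
#'
#' Walks an indexed dataset (see [index_dataset()]), segments every RGB
#' image, extracts geometry traits, and returns a long table keyed by
#' plant, day, view and trait. Days on which no plant pixels are found
#' yield `NA` values (not zeros), matching the pre-emergence convention.
#' Unreadable images are recorded as `NA` rows with a warning.
#'
#' @param root Dataset root directory (layout as written by
#'   [simulate_experiment()]).
#' @param calib A [zoom_calibration()] whose schedule covers all indexed
#'   days.
#' @param threshold Green-index threshold (default 1.15).
#' @param exclusions Exclusion rectangles passed to [segment_plant()].
#' @return Long data frame: `pot_id`, `genotype`, `day`, `view`, `trait`,
#'   `value`, with traits `height_px`, `width_px`, `area_px`,
#'   `height_mm`, `width_mm`, `area_adj`, `area_mm2` (side views; the top
#'   view has no mm calibration and reports pixel traits only).
#' @export
build_trait_timeseries <- function(root, calib = zoom_calibration(),
                                   threshold = 1.15, exclusions = list()) {
  idx <- index_dataset(root)
  rgb <- idx[idx$camera == "RGB", , drop = FALSE]
  if (nrow(rgb) == 0L) stop("no RGB images under ", root)
  px_traits <- c("height_px", "width_px", "area_px")
  mm_traits <- c("height_mm", "width_mm", "area_adj", "area_mm2")
  out <- vector("list", nrow(rgb))
  n_fail <- 0L
  for (i in seq_len(nrow(rgb))) {
    rec <- rgb[i, ]
    geo <- tryCatch({
      img <- read_raster(rec$path, view = rec$view, day = rec$day)
      mask <- segment_plant(img, threshold, exclusions)
      extract_geometry(mask, calib, rec$day)
    }, error = function(e) {
      warning("failed to process ", rec$path, ": ", conditionMessage(e))
      n_fail <<- n_fail + 1L
      extract_geometry(structure(matrix(FALSE, 1, 1), is_na = TRUE),
                       calib, rec$day)
    })
    traits <- if (rec$view == "top") px_traits else c(px_traits, mm_traits)
    out[[i]] <- data.frame(
      pot_id = rec$pot_id, genotype = rec$genotype, day = rec$day,
      view = rec$view, trait = traits,
      value = as.numeric(geo[1, traits]),
      stringsAsFactors = FALSE
    )
  }
  if (n_fail == nrow(rgb)) stop("all RGB images failed to process")
  do.call(rbind, out)
}
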