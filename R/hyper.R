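#' Construct a hyperspectral cube
#'
#' A stack of per-wavelength grayscale planes plus the band-to-wavelength
#' map. Intensities are stored in `[0, 1]` (8-bit grid when read from
#' PNG); after [normalize_cube()] plant pixels hold reflectance-like
#' ratios and may exceed 1.
#'
#' @param planes Numeric array `c(height, width, bands)`.
#' @param wavelengths Strictly increasing numeric vector of band-centre
#'   wavelengths (nm), one per plane.
#' @return List of class `hyper_cube` with elements `planes`,
#'   `wavelengths`, and `normalized` (flag).
#' @export
hyper_cube <- function(planes, wavelengths) {
  stopifnot(is.array(planes), length(dim(planes)) == 3L)
  if (length(wavelengths) != dim(planes)[3]) {
    stop("wavelength count must equal band count")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(list(planes = planes, wavelengths = as.numeric(wavelengths),
                 normalized = FALSE),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<hyper_cube> %d x %d px, %d bands (%.1f-%.1f nm)%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Write / read a hyperspectral cube as per-band grayscale PNGs
#'
#' Each band is stored as one 8-bit grayscale PNG named
#' `band_BBB_WWWWWWWWnm.png` (band order and band-centre wavelength in the
#' file name), the on-disk dialect of the "one sub-image per wavelength"
#' day directory. Files written by [write_cube()] and read back by
#' [read_cube()] round-trip bit-exactly. Grayscale planes stored as
#' 3-channel images with identical channels are accepted on read.
#'
#' @param cube A [hyper_cube()]; intensities must lie in `[0, 1]`.
#' @param dir Day directory holding (or to hold) the band files.
#' @return `read_cube()` returns a [hyper_cube()]; `write_cube()` returns
#'   `dir` invisibly.
#' @export
write_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (min(cube$planes) < 0 || max(cube$planes) > 1) {
    stop("cube intensities must lie in [0, 1] for 8-bit storage")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in seq_along(cube$wavelengths)) {
    fn <- file.path(dir, sprintf("band_%03d_%08.2fnm.png",
                                 b, cube$wavelengths[b]))
    png::writePNG(cube$planes[, , b], target = fn)
  }
  invisible(dir)
}

#' @rdname write_cube
#' @param expected_bands Optional band count to enforce; missing band
#'   indices are reported by name.
#' @export
read_cube <- function(dir, expected_bands = NULL) {
  files <- list.files(dir, pattern = "^band_\\d+_.*nm\\.png$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no band files found under ", dir)
  band_no <- as.integer(sub("^band_(\\d+)_.*$", "\\1", basename(files)))
  wl <- as.numeric(sub("^band_\\d+_(.*)nm\\.png$", "\\1", basename(files)))
  ord <- order(band_no)
  files <- files[ord]; band_no <- band_no[ord]; wl <- wl[ord]
  n <- expected_bands %||% max(band_no)
  missing <- setdiff(seq_len(n), band_no)
  if (length(missing) > 0L) {
    stop("missing band file(s) for band index: ",
         paste(missing, collapse = ", "))
  }
  planes <- NULL
  for (k in seq_along(files)) {
    px <- png::readPNG(files[k])
    if (!is.matrix(px)) {
      if (length(dim(px)) == 3L && dim(px)[3] >= 3L) {
        if (max(abs(px[, , 1] - px[, , 2])) > 0 ||
            max(abs(px[, , 1] - px[, , 3])) > 0) {
          stop("band ", band_no[k], " is not grayscale ",
               "(channels differ)")
        }
        px <- px[, , 1]
      } else stop("unsupported PNG shape for band ", band_no[k])
    }
    if (is.null(planes)) {
      planes <- array(0, c(nrow(px), ncol(px), length(files)))
    } else if (!all(dim(px) == dim(planes)[1:2])) {
      stop("band ", band_no[k], " has inconsistent dimensions")
    }
    planes[, , k] <- px
  }
  hyper_cube(planes, wl)
}

#' Band index nearest a target wavelength
#'
#' @param cube A [hyper_cube()].
#' @param target_nm Wavelength in nanometres; must lie within the cube's
#'   wavelength range.
#' @return 1-based band index of the nearest band centre; ties break
#'   toward the lower index.
#' @export
band_for_wavelength <- function(cube, target_nm) {
  wl <- cube$wavelengths
  if (target_nm < min(wl) || target_nm > max(wl)) {
    stop(sprintf("wavelength %g nm outside cube range [%g, %g]",
                 target_nm, min(wl), max(wl)))
  }
  d <- abs(wl - target_nm)
  which(d == min(d))[1]  # tie -> lower index
}

#' Segment plant pixels from a hyperspectral cube by NDVI
#'
#' Computes the normalized difference vegetation index
#' `(R750 - R705) / (R750 + R705)` from the bands nearest 750 nm and
#' 705 nm and marks as plant every pixel with NDVI strictly greater than
#' `threshold`. A zero denominator defines NDVI as 0 (background).
#'
#' @param cube A [hyper_cube()].
#' @param threshold NDVI cutoff (default 0.25, strict).
#' @return Logical plant mask with `is_na` attribute, as in
#'   [segment_plant()].
#' @export
segment_plant_ndvi <- function(cube, threshold = 0.25) {
  ndvi <- ndvi_map(cube)
  mask <- ndvi > threshold
  attr(mask, "is_na") <- !any(mask)
  mask
}

#' @rdname segment_plant_ndvi
#' @return `ndvi_map()` returns the per-pixel NDVI matrix.
#' @export
ndvi_map <- function(cube) {
  r750 <- cube$planes[, , band_for_wavelength(cube, 750)]
  r705 <- cube$planes[, , band_for_wavelength(cube, 705)]
  s <- r750 + r705
  ifelse(s == 0, 0, (r750 - r705) / s)
}

#' Separate stem from leaf within the plant mask
#'
#' Stem pixels are plant pixels whose reflectance ratio
#' `R1056 / R1151` is strictly greater than `threshold` (maize stems are
#' brighter near 1056 nm relative to 1151 nm than leaves); leaf pixels are
#' the remaining plant pixels, so stem and leaf always partition the
#' plant mask. A zero `R1151` with positive `R1056` counts as stem
#' (infinite ratio); both zero counts as leaf.
#'
#' @param cube A [hyper_cube()].
#' @param plant_mask Plant mask from [segment_plant_ndvi()].
#' @param threshold Ratio cutoff (default 1.2, strict).
#' @return List with logical `stem` and `leaf` masks.
#' @export
segment_stem <- function(cube, plant_mask, threshold = 1.2) {
  r1056 <- cube$planes[, , band_for_wavelength(cube, 1056)]
  r1151 <- cube$planes[, , band_for_wavelength(cube, 1151)]
  ratio <- ifelse(r1151 == 0, ifelse(r1056 > 0, Inf, 0), r1056 / r1151)
  stem <- plant_mask & (ratio > threshold)
  list(stem = stem, leaf = plant_mask & !stem)
}

#' Normalize a cube against its own background
#'
#' Divides each plant pixel's intensity, band by band, by the mean
#' intensity of the non-plant pixels of the same band in the same image.
#' Background pixels pass through unchanged. Because a global illumination
#' change scales plant and background alike, normalized plant values are
#' invariant to per-image illumination drift -- the purpose of the
#' correction.
#'
#' @param cube A [hyper_cube()].
#' @param plant_mask Logical plant mask.
#' @param stat Background statistic: `"mean"` (default) or `"median"`.
#' @return A [hyper_cube()] with `normalized = TRUE`.
#' @export
normalize_cube <- function(cube, plant_mask, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  bg <- !plant_mask
  if (!any(bg)) stop("normalization needs at least one non-plant pixel")
  planes <- cube$planes
  for (b in seq_len(dim(planes)[3])) {
    pl <- planes[, , b]
    m <- if (stat == "mean") mean(pl[bg]) else stats::median(pl[bg])
    if (m == 0) {
      stop(sprintf("background %s is zero in band %d (%.2f nm)",
                   stat, b, cube$wavelengths[b]))
    }
    pl[plant_mask] <- pl[plant_mask] / m
    planes[, , b] <- pl
  }
  out <- hyper_cube(planes, cube$wavelengths)
  out$normalized <- TRUE
  out
}

#' False-colour rendering of the first three spectral principal components
#'
#' Fits a PCA on the pooled plant-pixel-by-band matrix of one or more
#' (normally background-normalized) cubes, centred per band, and renders
#' each cube as an RGB image: the first principal component in the red
#' channel, the second in green, the third in blue. Per component, scores
#' are min-max rescaled to `[0, 1]` over the pooled pixels
#' (`(x - min) / (max - min)`) and quantized to 0--255 (round half up).
#' Non-plant pixels are black. Fitting jointly across cubes makes false
#' colours comparable between plants; set `pool = FALSE` to fit each cube
#' separately.
#'
#' @param cubes A [hyper_cube()] or list of them.
#' @param masks Matching plant mask or list of masks.
#' @param n_components Number of components to render (default 3).
#' @param pool Fit one PCA across all cubes (default) or per cube.
#' @return A [raster_image()] (or list of them, one per cube). A constant
#'   component (max equal to min) renders as a zero channel with a
#'   warning.
#' @export
pca_false_color <- function(cubes, masks, n_components = 3L, pool = TRUE) {
  single <- inherits(cubes, "hyper_cube")
  if (single) { cubes <- list(cubes); masks <- list(masks) }
  stopifnot(length(cubes) == length(masks))
  if (!pool && length(cubes) > 1L) {
    out <- mapply(function(cb, mk) {
      pca_false_color(cb, mk, n_components = n_components)
    }, cubes, masks, SIMPLIFY = FALSE)
    return(out)
  }
  mats <- mapply(function(cb, mk) {
    nb <- dim(cb$planes)[3]
    m <- matrix(0, sum(mk), nb)
    for (b in seq_len(nb)) m[, b] <- cb$planes[, , b][mk]
    m
  }, cubes, masks, SIMPLIFY = FALSE)
  X <- do.call(rbind, mats)  # pooled pixels x bands
  if (nrow(X) < n_components) {
    stop("need at least ", n_components, " plant pixels to fit the PCA")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scaled <- matrix(0, nrow(scores), n_components)
  for (j in seq_len(k)) {
    rng <- range(scores[, j])
    if (diff(rng) == 0) {
      warning("principal component ", j,
              " is constant; channel set to 0")
    } else {
      scaled[, j] <- (scores[, j] - rng[1]) / diff(rng)
    }
  }
  channel_vals <- quantize8(scaled) * 255
  offsets <- c(0L, cumsum(vapply(masks, function(m) sum(m), 0L)))
  out <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    d <- dim(cubes[[i]]$planes)[1:2]
    img <- array(0, c(d, 3L))
    if (offsets[i + 1L] > offsets[i]) {
      rows <- (offsets[i] + 1L):offsets[i + 1L]
      for (ch in seq_len(min(3L, n_components))) {
        pl <- matrix(0, d[1], d[2])
        pl[masks[[i]]] <- channel_vals[rows, ch]
        img[, , ch] <- pl
      }
    }
    out[[i]] <- raster_image(img, view = "side0", day = 1L, zoom = 1L)
  }
  if (single) out[[1]] else out
}

#' Mean spectrum over a tissue mask
#'
#' @param cube A [hyper_cube()].
#' @param mask Logical mask with at least one pixel set.
#' @param tissue Label recorded in the output (`"plant"`, `"stem"`,
#'   `"leaf"`, ...).
#' @return Data frame of class `spectral_summary`: `tissue`,
#'   `wavelength_nm`, `mean_intensity`, `n_pixels`.
#' @export
mean_spectrum <- function(cube, mask, tissue = "plant") {
  n <- sum(mask)
  if (n == 0L) stop("mean_spectrum needs a non-empty mask")
  means <- apply(cube$planes, 3, function(pl) mean(pl[mask]))
  out <- data.frame(tissue = tissue, wavelength_nm = cube$wavelengths,
                    mean_intensity = means, n_pixels = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("spectral_summary", "data.frame")
  out
}
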