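#' Segment plant pixels from a fluorescence image
#'
#' Fluorescence images carry nearly all signal in the red channel. Within
#' a zoom-specific region of interest (which on real images excludes the
#' pot and non-uniform chamber areas), every pixel whose red-channel
#' intensity is strictly greater than `threshold` is a plant pixel.
#'
#' @param image A [raster_image()] or `h x w x 3` array of 0--255
#'   intensities.
#' @param roi Region of interest rectangle `c(rmin, rmax, cmin, cmax)`,
#'   1-based inclusive; default `NULL` uses the full canvas.
#' @param threshold Red-channel cutoff (default 70, strict).
#' @return Logical plant mask with `is_na` attribute (set when no pixel
#'   passes).
#' @export
segment_fluorescence <- function(image, roi = NULL, threshold = 70) {
  x <- unclass(image)
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  mask <- x[, , 1] > threshold
  if (!is.null(roi)) {
    roi <- check_rect(roi, dim(mask), "region of interest")
    mask <- mask & rect_to_mask(dim(mask), roi)
  }
  attr(mask, "is_na") <- !any(mask)
  mask
}

#' Aggregate and mean fluorescence intensity
#'
#' The aggregate fluorescence intensity is the sum of red-channel values
#' over all plant pixels; the mean intensity is the aggregate divided by
#' the plant-pixel count. An empty mask yields an all-`NA` result.
#'
#' @param mask Plant mask from [segment_fluorescence()].
#' @param image The fluorescence [raster_image()] the mask was derived
#'   from (dimensions must match).
#' @return List of class `fluor_result`: `aggregate_intensity`,
#'   `mean_intensity`, `n_pixels`, `is_na`.
#' @examples
#' img <- array(0, c(1, 2, 3)); img[1, , 1] <- c(100, 71)
#' m <- segment_fluorescence(img)
#' fluorescence_intensity(m, img)  # aggregate 171, mean 85.5
#' @export
fluorescence_intensity <- function(mask, image) {
  x <- unclass(image)
  if (!all(dim(mask) == dim(x)[1:2])) {
    stop("mask and image dimensions differ")
  }
  if (is_na_mask(mask)) {
    res <- list(aggregate_intensity = NA_real_, mean_intensity = NA_real_,
                n_pixels = NA_integer_, is_na = TRUE)
  } else {
    red <- x[, , 1]
    agg <- sum(red[mask])
    n <- sum(mask)
    res <- list(aggregate_intensity = agg, mean_intensity = agg / n,
                n_pixels = as.integer(n), is_na = FALSE)
  }
  class(res) <- "fluor_result"
  res
}

#' @export
print.fluor_result <- function(x, ...) {
  if (x$is_na) cat("<fluor_result> NA (no plant pixels)\n")
  else cat(sprintf("<fluor_result> aggregate %g, mean %.2f over %d px\n",
                   x$aggregate_intensity, x$mean_intensity, x$n_pixels))
  invisible(x)
}
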