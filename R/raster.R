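#' Construct a raster image
#'
#' Lightweight container for an 8-bit RGB raster: a `height x width x 3`
#' numeric array with intensities in 0--255 plus imaging metadata carried
#' as attributes.
#'
#' @param channels Numeric array `c(height, width, 3)` of red, green and
#'   blue intensities in `[0, 255]`.
#' @param view Camera view label: `"side0"`, `"side90"` or `"top"`.
#' @param day Imaging-day index.
#' @param zoom Zoom level, 1 or 2.
#' @return The array with class `raster_image`.
#' @export
raster_image <- function(channels, view = "side0", day = 1L, zoom = 1L) {
  stopifnot(is.array(channels), length(dim(channels)) == 3L,
            dim(channels)[3] == 3L)
  if (min(channels) < 0 || max(channels) > 255) {
    stop("channel intensities must lie in [0, 255]")
  }
  if (!view %in% c("side0", "side90", "top")) stop("unknown view: ", view)
  if (!zoom %in% c(1L, 2L)) stop("zoom level must be 1 or 2")
  structure(channels, class = "raster_image",
            view = view, day = as.integer(day), zoom = as.integer(zoom))
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image> %d x %d px, view %s, day %d, zoom %d\n",
              d[1], d[2], attr(x, "view"), attr(x, "day"), attr(x, "zoom")))
  invisible(x)
}

#' Read / write an 8-bit RGB raster as PNG
#'
#' @param path PNG file path.
#' @param view,day,zoom Metadata attached to the returned raster (PNG does
#'   not carry them).
#' @return `read_raster()` returns a [raster_image()]; grayscale files are
#'   expanded to three identical channels.
#' @export
read_raster <- function(path, view = "side0", day = 1L, zoom = 1L) {
  px <- png::readPNG(path)
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  raster_image(round(px * 255), view = view, day = day, zoom = zoom)
}

#' @rdname read_raster
#' @param image A [raster_image()] (or bare array, 0--255).
#' @export
write_raster <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}
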