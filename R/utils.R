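# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation helpers stay pure.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-object seed stream: combines a base seed with small
# integer tags. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(base, ...) {
  tags <- c(...)
  s <- as.double(base) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.double(t) * 1000003 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Rectangles are length-4 integer vectors c(rmin, rmax, cmin, cmax),
# 1-based inclusive, rows = y (top to bottom), cols = x.
check_rect <- function(rect, dim = NULL, what = "rectangle") {
  if (!is.numeric(rect) || length(rect) != 4L || anyNA(rect)) {
    stop(sprintf("malformed %s: need c(rmin, rmax, cmin, cmax)", what))
  }
  if (rect[1] > rect[2] || rect[3] > rect[4]) {
    stop(sprintf("malformed %s: min exceeds max", what))
  }
  if (!is.null(dim)) {
    if (rect[1] < 1 || rect[2] > dim[1] || rect[3] < 1 || rect[4] > dim[2]) {
      stop(sprintf("%s c(%s) outside image bounds %d x %d",
                   what, paste(rect, collapse = ","), dim[1], dim[2]))
    }
  }
  invisible(as.integer(rect))
}

rect_to_mask <- function(dim, rect) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rect[1]:rect[2], rect[3]:rect[4]] <- TRUE
  m
}

# Quantize intensities in [0, 1] to the 8-bit grid k/255, round half up.
quantize8 <- function(x) {
  pmin(pmax(floor(x * 255 + 0.5), 0), 255) / 255
}

`%||%` <- function(a, b) if (is.null(a)) b else a
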