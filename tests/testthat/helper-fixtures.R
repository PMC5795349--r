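# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# A tiny solid-colour RGB image (0-255 intensities).
solid_rgb <- function(r, g, b, h = 4L, w = 5L) {
  img <- array(0, c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

# Random RGB image for oracle-equivalence checks.
random_rgb <- function(h = 100L, w = 100L) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

# Naive per-pixel green-index segmentation (independent oracle).
naive_green_mask <- function(img, threshold = 1.15) {
  h <- dim(img)[1]; w <- dim(img)[2]
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- img[i, j, 1]; g <- img[i, j, 2]; b <- img[i, j, 3]
    gi <- if (r + b == 0) (if (g > 0) Inf else 0) else 2 * g / (r + b)
    m[i, j] <- gi > threshold
  }
  m
}

# A small hypercube with hand-set band values at chosen wavelengths.
# `bands` is a named list wavelength -> matrix.
toy_cube <- function(bands) {
  wl <- as.numeric(names(bands))
  dims <- dim(bands[[1]])
  planes <- array(0, c(dims, length(bands)))
  for (k in seq_along(bands)) planes[, , k] <- bands[[k]]
  hyper_cube(planes, wl)
}

# Sub-design restricted to a set of genotypes (class preserved).
sub_design <- function(design, genotypes) {
  out <- design[!design$is_empty & design$genotype %in% genotypes, ]
  class(out) <- class(design)
  out
}

# Permutation null for the genotype error fraction: shuffle residuals
# across plants, keeping the design fixed.
perm_null_fractions <- function(residuals, genotype, replicate, n = 100L,
                                seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    error_heritability(sample(residuals), genotype, replicate)
  }, 0)
}
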