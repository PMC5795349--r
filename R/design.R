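#' Reference greenhouse layout for the ZL maize diversity panel
#'
#' The bundled 10-row by 16-column pot grid used by the greenhouse
#' experiment this package models: 156 plants drawn from 32 inbred
#' genotypes (`ZL1`--`ZL32`) plus 4 empty control pots (soil only, used as
#' evaporation controls). Sequential pairs of rows form a complete
#' replicate; within each replicate, genotypes are blocked in groups of 8
#' (one half row). Genotype `ZL22` is present as a single unreplicated
#' plant.
#'
#' @return An integer matrix with 10 rows and 16 columns; entries are the
#'   genotype numbers 1--32, with `NA` marking empty control pots.
#' @export
zl_grid_layout <- function() {
  g <- c(
     9,  7,  3, 10, 23, 25, 26, 19, 13,  5, 29, 21,  2,  4, 18, 20,
    11, 16,  1, 32, 17, 27,  6, 22, 24, 31, 14, 30, 15, 28,  8, 12,
    29, 31, 15, 13,  1, 17, 25,  9, 21, 30,  3,  5, NA, 19, 14,  6,
    12, 23, 32, 16,  7, 28,  2, 18, 10, 11,  8, 26, 27,  4, 20, 24,
    25,  9, 21, 27, 28, 12,  5, 11, 15,  6, NA,  7,  4, 23, 31, 20,
    19, 32, 29, 24, 16, 13,  3,  8, 17, 14, 18, 30, 10, 26,  1,  2,
     8,  1, 17, 23, 21,  5,  7, 24, 27, 18,  3, 11, 31, 15, 19,  2,
    25, 30,  4,  9, 16, 32, 14, 20, NA, 10,  6, 29, 28, 12, 26, 13,
    15, 10,  5, 32, 31, 21, 16, 26,  2, 18,  9, 25,  6,  8, 24, NA,
    29, 13, 23, 14, 27,  7, 11, 30, 12,  1, 28,  4,  3, 20, 17, 19
  )
  matrix(as.integer(g), nrow = 10, ncol = 16, byrow = TRUE)
}

#' Generate a randomized experimental design
#'
#' Builds the full pot-level design table for the 10 x 16 greenhouse grid.
#' The genotype content of each randomization block (a half row of 8
#' contiguous pots, including any empty control pot) is fixed by the
#' reference layout; the order of pots *within* each block is a
#' deterministic permutation driven by `seed`. This preserves every design
#' invariant -- 156 occupied pots, 4 empties, one replicate per sequential
#' row pair, at most one plant of each genotype per replicate, and a single
#' `ZL22` plant -- while re-randomizing block order between runs.
#'
#' @param seed Integer seed controlling the within-block permutations.
#'   `seed = 0` reproduces the reference layout order exactly as bundled.
#' @param layout Optional 10 x 16 integer matrix of genotype numbers with
#'   `NA` for empty pots; defaults to [zl_grid_layout()].
#' @return A data frame of class `experiment_design` with one row per pot:
#'   `pot_id` (zero-padded position label), `row`, `col`, `genotype`
#'   (`"ZL1"`..`"ZL32"` or `NA` for empty pots), `replicate` (1--5),
#'   `block` (1--4 within replicate), and `is_empty`.
#' @examples
#' d <- generate_design(seed = 0)
#' sum(!d$is_empty)                      # 156 plants
#' length(unique(na.omit(d$genotype)))   # 32 genotypes
#' @export
generate_design <- function(seed = 0L, layout = zl_grid_layout()) {
  stopifnot(is.matrix(layout), nrow(layout) == 10L, ncol(layout) == 16L)
  grid <- layout
  if (seed != 0L) {
    grid <- with_local_seed(derive_seed(seed, 7L), {
      g <- layout
      for (r in seq_len(nrow(g))) {
        for (half in c(0L, 8L)) {
          cols <- half + 1:8
          g[r, cols] <- g[r, sample(cols)]
        }
      }
      g
    })
  }
  idx <- expand.grid(col = 1:16, row = 1:10)[, c("row", "col")]
  geno_num <- grid[cbind(idx$row, idx$col)]
  design <- data.frame(
    pot_id = sprintf("%03d", seq_len(nrow(idx))),
    row = idx$row,
    col = idx$col,
    genotype = ifelse(is.na(geno_num), NA_character_,
                      paste0("ZL", geno_num)),
    replicate = (idx$row + 1L) %/% 2L,
    block = 2L * ((idx$row + 1L) %% 2L) + 1L + (idx$col > 8L),
    is_empty = is.na(geno_num),
    stringsAsFactors = FALSE
  )
  class(design) <- c("experiment_design", "data.frame")
  design
}

# Internal invariant checker; stops with an informative message on the
# first violated design property.
validate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (nrow(design) != 160L) stop("design must have exactly 160 grid cells")
  if (sum(design$is_empty) != 4L) stop("design must have exactly 4 empty pots")
  if (sum(!design$is_empty) != 156L) stop("design must have 156 occupied pots")
  genos <- design$genotype[!design$is_empty]
  if (length(unique(genos)) != 32L) stop("design must contain 32 genotypes")
  if (sum(genos == "ZL22") != 1L) stop("ZL22 must appear exactly once")
  if (!all(design$replicate == (design$row + 1L) %/% 2L)) {
    stop("replicates must be sequential row pairs")
  }
  per_rep <- table(design$replicate[!design$is_empty],
                   genos)
  if (any(per_rep > 1L)) stop("a genotype appears twice within a replicate")
  blk <- table(design$replicate, design$block)
  if (any(blk != 8L)) stop("each block must hold 8 contiguous half-row pots")
  invisible(TRUE)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %d pots (%d plants, %d empty), %d genotypes, %d replicates\n",
    nrow(x), sum(!x$is_empty), sum(x$is_empty),
    length(unique(stats::na.omit(x$genotype))), max(x$replicate)))
  invisible(x)
}
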