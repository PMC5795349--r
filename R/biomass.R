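#' Assemble the six image-derived biomass predictors
#'
#' Joins the final-day trait tables of the three processed camera types
#' into one row per plant with the six predictors used for biomass
#' modelling: zoom-adjusted plant pixels summed over the two RGB side
#' views (`side_pixels`), the same plus the top view
#' (`side_top_pixels`), aggregate fluorescence intensity over the two
#' side views (`fluor_side`) and with the top view (`fluor_side_top`),
#' and the hyperspectral stem and leaf pixel counts -- plus the measured
#' fresh biomass response. Plants missing a modality are kept but flagged
#' incomplete.
#'
#' @param rgb_traits Long RGB trait table (see [build_trait_timeseries()])
#'   restricted to, or filtered here to, the assembly day.
#' @param fluor_table Data frame `pot_id`, `view`, `aggregate_intensity`.
#' @param hyper_table Data frame `pot_id`, `stem_pixels`, `leaf_pixels`.
#' @param biomass Data frame `pot_id`, `fresh_biomass_g` (ground truth).
#' @param design An [generate_design()] table supplying genotype and
#'   replicate.
#' @param day Day whose records to assemble (default: the latest day in
#'   `rgb_traits`).
#' @return Data frame of class `biomass_features`.
#' @export
assemble_features <- function(rgb_traits, fluor_table, hyper_table,
                              biomass, design,
                              day = max(rgb_traits$day)) {
  rt <- rgb_traits[rgb_traits$day == day, , drop = FALSE]
  pots <- unique(rt$pot_id)
  pots <- pots[pots %in% biomass$pot_id]
  if (length(pots) == 0L) {
    stop("no plants shared between trait tables and biomass records")
  }
  val <- function(pot, view, trait) {
    v <- rt$value[rt$pot_id == pot & rt$view == view & rt$trait == trait]
    if (length(v) == 0L) NA_real_ else v[1]
  }
  fl <- function(pot, view) {
    v <- fluor_table$aggregate_intensity[
      fluor_table$pot_id == pot & fluor_table$view == view]
    if (length(v) == 0L) NA_real_ else v[1]
  }
  rows <- lapply(pots, function(p) {
    hy <- hyper_table[hyper_table$pot_id == p, , drop = FALSE]
    d <- design[design$pot_id == p, , drop = FALSE]
    side <- val(p, "side0", "area_adj") + val(p, "side90", "area_adj")
    data.frame(
      pot_id = p,
      genotype = if (nrow(d)) d$genotype else NA_character_,
      replicate = if (nrow(d)) d$replicate else NA_integer_,
      side_pixels = side,
      side_top_pixels = side + val(p, "top", "area_px"),
      fluor_side = fl(p, "side0") + fl(p, "side90"),
      fluor_side_top = fl(p, "side0") + fl(p, "side90") + fl(p, "top"),
      stem_pixels = if (nrow(hy)) hy$stem_pixels[1] else NA_real_,
      leaf_pixels = if (nrow(hy)) hy$leaf_pixels[1] else NA_real_,
      fresh_biomass_g =
        biomass$fresh_biomass_g[match(p, biomass$pot_id)],
      stringsAsFactors = FALSE
    )
  })
  feats <- do.call(rbind, rows)
  feats$complete <- stats::complete.cases(
    feats[, c("side_pixels", "side_top_pixels", "fluor_side",
              "fluor_side_top", "stem_pixels", "leaf_pixels",
              "fresh_biomass_g")])
  class(feats) <- c("biomass_features", "data.frame")
  feats
}

.BIOMASS_PREDICTORS <- c("side_pixels", "side_top_pixels", "fluor_side",
                         "fluor_side_top", "stem_pixels", "leaf_pixels")

#' Fit a biomass prediction model
#'
#' The univariate model regresses fresh biomass on the zoom-adjusted
#' side-view pixel count alone; multivariate methods use all six
#' image-derived predictors. Predictions and residuals are in-sample
#' (no cross-validation), matching how fit correlations are usually
#' reported for these models; residuals are `measured - predicted`.
#' Stochastic learners are seeded for exact reproducibility.
#'
#' @param features A [assemble_features()] (or [synthesize_features()])
#'   table; rows with missing fields are dropped.
#' @param method One of `"univariate_linear"`, `"multivariate_linear"`,
#'   `"random_forest"` (needs the randomForest package), `"svm"` (needs
#'   e1071).
#' @param seed Integer seed for stochastic methods (default 1).
#' @return List of class `biomass_fit`: `method`, `pot_id`, `predicted`,
#'   `measured`, `residuals`, `r` (Pearson correlation of predicted and
#'   measured), and the underlying `model` object.
#' @export
fit_biomass <- function(features,
                        method = c("univariate_linear",
                                   "multivariate_linear",
                                   "random_forest", "svm"),
                        seed = 1L) {
  method <- match.arg(method)
  need <- c(.BIOMASS_PREDICTORS, "fresh_biomass_g")
  dat <- features[stats::complete.cases(features[, need]), , drop = FALSE]
  if (nrow(dat) < 10L) {
    stop("need at least 10 complete feature rows; got ", nrow(dat))
  }
  y <- dat$fresh_biomass_g
  model <- switch(
    method,
    univariate_linear = stats::lm(fresh_biomass_g ~ side_pixels,
                                  data = dat),
    multivariate_linear = stats::lm(
      stats::reformulate(.BIOMASS_PREDICTORS, "fresh_biomass_g"),
      data = dat),
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("method 'random_forest' needs the randomForest package")
      }
      with_local_seed(seed, randomForest::randomForest(
        x = dat[, .BIOMASS_PREDICTORS], y = y))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("method 'svm' needs the e1071 package")
      }
      with_local_seed(seed, e1071::svm(
        x = dat[, .BIOMASS_PREDICTORS], y = y))
    }
  )
  pred <- switch(method,
                 univariate_linear = ,
                 multivariate_linear = unname(stats::fitted(model)),
                 unname(stats::predict(model,
                                       dat[, .BIOMASS_PREDICTORS])))
  res <- list(method = method, pot_id = dat$pot_id,
              genotype = dat$genotype, replicate = dat$replicate,
              predicted = pred, measured = y,
              residuals = y - pred,
              r = if (stats::sd(pred) == 0 || stats::sd(y) == 0)
                NA_real_ else stats::cor(pred, y),
              model = model)
  class(res) <- "biomass_fit"
  res
}

#' @export
print.biomass_fit <- function(x, ...) {
  cat(sprintf("<biomass_fit> %s on %d plants, fit r = %.4f\n",
              x$method, length(x$measured), x$r))
  invisible(x)
}

#' Fraction of biomass-prediction error explained by genotype
#'
#' Fits the replicate-plus-genotype ANOVA to the per-plant residuals of a
#' biomass model and returns the genotype share of the residual sum of
#' squares, `SS_genotype / (SS_error + SS_genotype)`. A fraction well
#' above its permutation null means the model's errors are systematic by
#' genotype -- some lines consistently over- or under-predicted -- which
#' is what genotype-dependent tissue density produces in any
#' density-blind, pixel-based predictor.
#'
#' @param result A [fit_biomass()] result.
#' @param design Optional [generate_design()] table used to fill in
#'   genotype/replicate when absent from the fit.
#' @return Fraction in `[0, 1]` (or `NA` when the residuals are exactly
#'   zero everywhere, as for a saturated noise-free fit).
#' @export
genotype_error_fraction <- function(result, design = NULL) {
  stopifnot(inherits(result, "biomass_fit"))
  genotype <- result$genotype
  replicate <- result$replicate
  if ((is.null(genotype) || is.null(replicate)) && !is.null(design)) {
    m <- match(result$pot_id, design$pot_id)
    genotype <- design$genotype[m]
    replicate <- design$replicate[m]
  }
  if (is.null(genotype) || is.null(replicate)) {
    stop("genotype and replicate are required (supply `design`)")
  }
  error_heritability(result$residuals, genotype, replicate)
}
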