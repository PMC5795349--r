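#' Per-day ANOVA decomposition for a trait
#'
#' Fits the per-day linear model `value ~ environment + genotype` by least
#' squares and returns sequential (type-I) sums of squares, with the
#' environment term -- greenhouse `row` or `replicate` -- entered before
#' genotype. The `genotype_only` model drops the environment term, so its
#' error sum of squares absorbs positional variation; comparing the two is
#' what separates the row-adjusted from the classical heritability.
#' `NA` values are dropped, and genotypes left with fewer than two
#' observations (such as the single-plant genotype ZL22) are excluded
#' before fitting, since unreplicated genotypes contribute no
#' within-genotype error information.
#'
#' @param observations Data frame with columns `value` and `genotype`,
#'   plus `row` or `replicate` as required by `model`.
#' @param model `"row_genotype"` (default), `"genotype_only"`, or
#'   `"replicate_genotype"`.
#' @return List of class `heritability_fit`: `model`, `ss_env`,
#'   `ss_genotype`, `ss_error`, `ss_total`, `df` (named vector),
#'   `n_obs`, `n_genotypes`, `n_dropped` (NA or unreplicated rows
#'   removed).
#' @examples
#' obs <- data.frame(genotype = c("A", "A", "B", "B"),
#'                   value = c(0, 2, 2, 4))
#' fit <- anova_day(obs, model = "genotype_only")
#' fit$ss_genotype  # 4
#' fit$ss_error     # 4
#' @export
anova_day <- function(observations,
                      model = c("row_genotype", "genotype_only",
                                "replicate_genotype")) {
  model <- match.arg(model)
  obs <- observations
  stopifnot(all(c("value", "genotype") %in% names(obs)))
  env_var <- switch(model, row_genotype = "row",
                    replicate_genotype = "replicate",
                    genotype_only = NULL)
  if (!is.null(env_var) && !env_var %in% names(obs)) {
    stop("model '", model, "' needs column '", env_var, "'")
  }
  n_in <- nrow(obs)
  obs <- obs[is.finite(obs$value), , drop = FALSE]
  counts <- table(obs$genotype)
  keep <- names(counts)[counts >= 2L]
  obs <- obs[obs$genotype %in% keep, , drop = FALSE]
  n_dropped <- n_in - nrow(obs)
  if (length(unique(obs$genotype)) < 2L) {
    stop("need at least 2 replicated genotypes after filtering")
  }
  obs$genotype <- factor(obs$genotype)
  env_constant <- FALSE
  form <- if (is.null(env_var)) {
    value ~ genotype
  } else {
    obs[[env_var]] <- factor(obs[[env_var]])
    if (nlevels(obs[[env_var]]) < 2L) {
      # a constant environment term carries no variation; its SS is 0
      env_constant <- TRUE
      value ~ genotype
    } else {
      stats::as.formula(paste("value ~", env_var, "+ genotype"))
    }
  }
  fit <- stats::lm(form, data = obs)
  if (!is.null(env_var) && !env_constant) {
    alias <- stats::alias(fit)$Complete
    if (!is.null(alias)) {
      stop("singular design: aliased terms ",
           paste(rownames(alias), collapse = ", "))
    }
  }
  # F-tests are not used, only the SS column; suppress the "perfect fit"
  # warning that noise-free fixtures trigger
  tab <- suppressWarnings(stats::anova(fit))
  ss <- stats::setNames(tab[["Sum Sq"]], rownames(tab))
  dfs <- stats::setNames(tab[["Df"]], rownames(tab))
  out <- list(
    model = model,
    ss_env = if (is.null(env_var)) NA_real_ else
      if (env_constant) 0 else unname(ss[env_var]),
    ss_genotype = unname(ss["genotype"]),
    ss_error = unname(ss["Residuals"]),
    ss_total = sum(ss),
    df = dfs, n_obs = nrow(obs),
    n_genotypes = nlevels(obs$genotype), n_dropped = n_dropped
  )
  class(out) <- "heritability_fit"
  out
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf(
    "<heritability_fit> model %s: SS env %.4g, genotype %.4g, error %.4g (n = %d)\n",
    x$model, x$ss_env, x$ss_genotype, x$ss_error, x$n_obs))
  invisible(x)
}

#' Broad-sense heritability from an ANOVA fit
#'
#' Two sum-of-squares ratios are supported. The *adjusted* heritability,
#' from the environment-plus-genotype model, is
#' `SS_genotype / (SS_error + SS_genotype)`: the share of non-positional
#' variation explained by genotype after the row (or replicate) effect has
#' been removed. The *classical* heritability, from the genotype-only
#' model, is `SS_genotype / SS_total`; its denominator still contains the
#' positional variation, which is why adjusting for rows typically raises
#' heritability.
#'
#' @param fit A [anova_day()] result.
#' @param kind `"adjusted"` (default) or `"classical"`. Classical
#'   heritability requires a `genotype_only` fit.
#' @return Heritability in `[0, 1]`, or `NA` (with a warning) when the
#'   denominator is zero.
#' @export
heritability <- function(fit, kind = c("adjusted", "classical")) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit, "heritability_fit"))
  if (kind == "classical") {
    if (fit$model != "genotype_only") {
      stop("classical heritability requires a genotype_only fit")
    }
    denom <- fit$ss_total
  } else {
    denom <- fit$ss_genotype + fit$ss_error
  }
  if (denom == 0) {
    warning("all sums of squares are zero; heritability undefined")
    return(NA_real_)
  }
  fit$ss_genotype / denom
}

#' Genotype share of residual variation
#'
#' Fits the replicate-plus-genotype sequential ANOVA to per-plant
#' residuals (for example biomass-prediction errors) and returns
#' `SS_genotype / (SS_error + SS_genotype)`: the fraction of residual
#' variation, after removing the replicate effect, that is systematic with
#' genotype rather than random. Unreplicated genotypes (ZL22) are dropped.
#'
#' @param residuals Numeric vector of per-plant residuals.
#' @param genotype,replicate Vectors aligned with `residuals`.
#' @return Fraction in `[0, 1]`, or `NA` when the residuals carry no
#'   variation at all.
#' @export
error_heritability <- function(residuals, genotype, replicate) {
  obs <- data.frame(value = residuals, genotype = genotype,
                    replicate = replicate, stringsAsFactors = FALSE)
  fit <- anova_day(obs, model = "replicate_genotype")
  # numerical-zero guard: a saturated upstream fit leaves residuals at
  # floating-point noise, whose SS carries no information
  if (fit$ss_genotype + fit$ss_error <= 1e-12) {
    warning("residuals carry no within-replicate variation; ",
            "fraction undefined")
    return(NA_real_)
  }
  heritability(fit, "adjusted")
}

#' Smooth a heritability time course
#'
#' Gaussian-kernel local-mean smoother on the day grid: each output value
#' is the kernel-weighted average of the raw series, with weights
#' `exp(-((day - day0) / bandwidth)^2 / 2)`. Endpoints use the naturally
#' truncated kernel. Because the output is a convex combination of the
#' input, smoothed values always stay within the range of the raw series,
#' and as `bandwidth` approaches zero the smoother returns the raw values.
#'
#' @param days Numeric vector of day indices (at least 3).
#' @param values Heritability values aligned with `days`; `NA`s are
#'   ignored in the averaging.
#' @param bandwidth Kernel bandwidth in days (default 2; must be
#'   positive).
#' @param grid Days at which to evaluate the smoother (default `days`).
#' @return Data frame `day`, `smoothed`.
#' @export
smooth_heritability <- function(days, values, bandwidth = 2,
                                grid = days) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (length(days) < 3L) stop("need at least 3 days to smooth")
  stopifnot(length(days) == length(values))
  ok <- is.finite(values)
  sm <- vapply(grid, function(d0) {
    w <- exp(-0.5 * ((days[ok] - d0) / bandwidth)^2)
    sum(w * values[ok]) / sum(w)
  }, 0)
  data.frame(day = grid, smoothed = sm)
}

#' Per-day heritability series for one trait
#'
#' Runs the adjusted and classical ANOVA decompositions for every day of
#' a long trait table and appends a smoothed adjusted-heritability curve.
#' Days whose fit fails (too few replicated genotypes after `NA` removal)
#' are reported with `NA` heritability.
#'
#' @param observations Long data frame with columns `day`, `value`,
#'   `genotype`, `row` (and optionally `replicate`).
#' @param bandwidth Smoothing bandwidth in days; see
#'   [smooth_heritability()].
#' @return Data frame of class `heritability_series`: per day, the
#'   sums of squares of the adjusted model, `hr_adjusted`,
#'   `hr_classical`, `n_obs`, and `hr_smoothed`.
#' @export
heritability_series <- function(observations, bandwidth = 2) {
  stopifnot(all(c("day", "value", "genotype", "row") %in%
                  names(observations)))
  days <- sort(unique(observations$day))
  rows <- lapply(days, function(d) {
    obs <- observations[observations$day == d, , drop = FALSE]
    adj <- tryCatch(anova_day(obs, "row_genotype"),
                    error = function(e) NULL)
    cls <- tryCatch(anova_day(obs, "genotype_only"),
                    error = function(e) NULL)
    data.frame(
      day = d,
      ss_row = if (is.null(adj)) NA_real_ else adj$ss_env,
      ss_genotype = if (is.null(adj)) NA_real_ else adj$ss_genotype,
      ss_error = if (is.null(adj)) NA_real_ else adj$ss_error,
      hr_adjusted = if (is.null(adj)) NA_real_ else
        suppressWarnings(heritability(adj, "adjusted")),
      hr_classical = if (is.null(cls)) NA_real_ else
        suppressWarnings(heritability(cls, "classical")),
      n_obs = if (is.null(adj)) 0L else adj$n_obs
    )
  })
  out <- do.call(rbind, rows)
  if (sum(is.finite(out$hr_adjusted)) >= 3L) {
    sm <- smooth_heritability(out$day, out$hr_adjusted, bandwidth)
    out$hr_smoothed <- sm$smoothed
  } else {
    out$hr_smoothed <- NA_real_
  }
  class(out) <- c("heritability_series", "data.frame")
  out
}
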