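---
title: "Models and methods behind phenomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

phenomap re-implements, as tested and reusable functions, the image
processing and statistical procedures of a greenhouse high-throughput
maize phenotyping experiment: a 10 x 16 pot grid carrying 156 plants of
32 inbred genotypes (plus 4 empty evaporation-control pots), imaged daily
by RGB, fluorescence and 243-band hyperspectral cameras. This vignette
explains the models the package implements, the choices made where the
procedures left details open, and what the bundled synthetic generator
does and does not demonstrate.

## Segmentation models

Three per-pixel index thresholds, each a *strict* inequality as the
procedures specify them:

* **RGB green index.** A pixel is plant when `2G / (R + B) > 1.15`.
  Degenerate pixels are defined explicitly: `R + B = 0` with `G > 0`
  maps to `Inf` (plant-like saturated green), all-zero maps to 0.
  Exclusion rectangles (for reflective chamber columns on real images)
  remove pixels after thresholding; the synthetic default is none.
* **Hyperspectral NDVI.** `(R750 - R705) / (R750 + R705) > 0.25`
  selects plant pixels, with bands resolved by nearest band-centre
  wavelength (ties toward the lower index). A zero denominator defines
  NDVI as 0, i.e. background.
* **Stem ratio.** Within the NDVI plant mask, `R1056 / R1151 > 1.2`
  selects stem pixels; leaf pixels are the complement within the plant
  mask, so stem and leaf always partition the plant exactly.
* **Fluorescence.** Within a zoom-specific region of interest, red
  channel `> 70` selects plant pixels; aggregate intensity is the sum of
  red values over those pixels and mean intensity the aggregate divided
  by the count.

An image with no passing pixel yields an `NA` mask, and `NA` propagates
to every derived trait; this is the convention for pre-emergence days
and is distinct from zero.

## Geometry and zoom calibration

Height and width are the y- and x-extents (inclusive) of the axis-aligned
minimum bounding box of the plant mask; area is the plant-pixel count.
Side-view cameras operate at two zoom levels with printed calibrations of
0.746 mm and 1.507 mm per pixel; `area_adj` re-expresses any area in
zoom-1-equivalent pixels via the squared calibration ratio so that days
imaged at different zooms are commensurable. The top view has no printed
calibration and is reported in pixels only. The campaign-style schedule
(`zoom_schedule_campaign()`) places one isolated zoom-2 day mid-campaign
and a terminal zoom-2 stretch, mirroring the acquisition history.

## Heritability model

For one trait and one day, observations follow the additive fixed-effects
model

y_ij = mu + alpha_row(i) + gamma_genotype(i,j) + epsilon_ij.

`anova_day()` fits this by least squares with *sequential* (type-I) sums
of squares, environment term entered before genotype — the order the
model states, and in a near-balanced design the ordering matters little.
Two statistics are derived:

* adjusted heritability `SS_gamma / (SS_epsilon + SS_gamma)` from the
  row-plus-genotype model;
* classical heritability `SS_gamma / SS_total` from the genotype-only
  model, whose denominator still contains row-to-row (positional)
  variation.

Both are fixed-effects SS ratios, not REML variance-component ratios.
Unreplicated genotypes (the single-plant genotype ZL22) are excluded
before fitting, as are `NA` observations, per day. The residual-error
variant (`error_heritability()`) replaces the row term by a replicate
term (a replicate is a sequential pair of rows) and is applied to
biomass-prediction residuals to measure how much prediction error is
systematic by genotype.

A property worth stating explicitly because it shapes expectations on
simulated data: the SS ratio is not an unbiased estimator of
`s2_g / (s2_g + s2_e)` at finite replication. For G genotypes with n
replicates, `E[SS_g] = (G-1) s2_e + N(1 - 1/G) s2_g` while
`E[SS_e] = (N-G) s2_e`, so with 31 replicated genotypes at n = 5 and
`s2_g = s2_e` the expected ratio is about 0.6, converging to 0.5 only as
n grows. The acceptance suite computes the simulated mean under exactly
these conditions and reports it as-is; the package does not re-scale the
statistic, because the ratio — not the variance-component estimand — is
the published definition.

The time course of heritability is smoothed with a Gaussian-kernel local
mean on the day grid (`smooth_heritability()`, bandwidth 2 days by
default). The smoother choice is ours; no particular method is named in
the source procedures. It preserves constants, stays within the range of
the raw series, and degenerates to the identity as the bandwidth shrinks.

## Hyperspectral normalization and false colour

Lighting performance drifts between images, so each plant pixel is
divided, band by band, by the mean intensity of the *non-plant* pixels in
the same band of the same image (`normalize_cube()`; the background
statistic is configurable to the median — the exact statistic used by the
released processing script is not printed, and the mean is the
conventional default). Because a global illumination factor scales plant
and background alike, it cancels exactly; the two index ratios are
likewise scale-invariant.

`pca_false_color()` fits a PCA on the pooled plant-pixel-by-band matrix,
centred per band and unscaled, and renders components 1 to 3 into the
red, green and blue channels after per-component min-max rescaling to
[0, 1] and 8-bit quantization (round half up). Pooling across cubes
(default) keeps colours comparable between plants; per-cube fitting is a
flag. Whether the published figures used normalized or raw intensities is
not stated; the default here is normalized, also behind a flag. A
constant component renders as a zero channel with a warning, and sign
indeterminacy of principal components means channel polarity may flip
between runs of different data — tests compare both orientations.

## Biomass models and error decomposition

Six predictors per plant: zoom-adjusted side-view plant pixels (the sum
of both side views), the same plus the top view, aggregate fluorescence
for the corresponding view sets, and hyperspectral stem and leaf pixel
counts. The univariate model regresses fresh biomass on side-view pixels
alone; multivariate linear, random forest and SVM adapters use all six.
Fits are in-sample, matching how fit correlations for such models are
customarily reported; a MARS adapter is not provided because no MARS
implementation is available in the supported dependency set.
`genotype_error_fraction()` feeds the residuals to the replicate-plus-
genotype ANOVA and returns the genotype share of residual variation.

The degenerate case matters: with exactly two genotypes and areas
constant within genotype, the univariate regression interpolates the two
(area, biomass) points, residuals are identically zero, and the fraction
is undefined (returned as `NA` with a warning). Three or more genotypes
with distinct densities make the fraction exactly 1 in the noise-free
case, which is the configuration the validation suite uses.

## The synthetic generator

The generator is an exact oracle, not a photorealistic simulator.

* **Design.** The genotype content of each randomization block (half-row
  of 8) is the bundled reference layout; `generate_design(seed)`
  permutes order within blocks only, so every invariant (156 plants, 4
  empties, one replicate per row pair, at most one plant per genotype
  per replicate, single ZL22) holds by construction.
* **Growth.** Height and width follow logistic day trends (sigmoid
  growth with emergence a few days in; the real campaign shows
  sigmoid-like curves but no functional form is printed) plus
  genotype, row, and plant-day effects with configurable variances.
  Defaults (100/25/25 px^2) give ~10 px genotype sd on a ~280 px plant —
  visible but noisy, a realistic mid-campaign regime.
* **Phantoms.** Stem = axis-aligned rectangle, leaves = rotated ellipses
  plus a full-width midrib, all clipped to the H x W bounding box, so
  truth height and width are exact by construction. Leaf arrangement is
  a deterministic function of the trait values, making plants with
  identical traits pixel-identical — which keeps the all-zero-variance
  case fully degenerate, as an oracle should be.
* **Spectra.** Leaf pixels carry a green-vegetation reflectance template
  (strong red-edge rise, water-absorption dips; NDVI ~ 0.57), stem
  pixels an elevated 1056 nm plateau (ratio ~ 1.4), background a flat
  spectrum (NDVI exactly 0). All templates clear their thresholds with
  wide margins, so 8-bit quantization and illumination scaling (a
  per-image lognormal scalar, log-sd 0.05 by default, clamped to
  [0.6, 1.4] to avoid clipping) never flip a pixel's class. The real
  instrument's wavelength grid is not published; a uniform 243-band grid
  over 546-1700 nm is assumed, with nearest-neighbour band lookup.
* **Biomass.** Fresh biomass is genotype-specific tissue density times
  adjusted area plus optional noise. The default density map spreads
  0.010-0.014 g per adjusted pixel across ZL1-ZL32 (~ +/- 17% around the
  mean, the order of real leaf-to-stem-ratio differences), which is what
  makes a density-blind pixel model systematically wrong by genotype.
* **Imaging days.** 29 by default: the campaign imaged daily over
  roughly five and a half weeks and the exact imaged-day count is not
  printed; 29 keeps a full sigmoid within the window.
* **Canvas.** 400 x 300 px for RGB/fluorescence (against the real
  2454 x 2056) and 100 x 75 for cubes; sizes are configuration, chosen
  so the full suite renders hundreds of scenes in seconds. Validation
  runs here use up to 100 scenes per property, 200 simulation replicates
  for heritability, and 15-40 plants for the biomass loops.

What passing on phantoms shows: the implementation applies the stated
formulas exactly (thresholds, strictness, calibration arithmetic, SS
decompositions), end to end through PNG round-trips. What it does not
show: robustness to the things real images have and phantoms lack —
soft leaf edges, specular pots, occlusion, sensor noise, non-uniform
illumination fields (drift here is a single global scalar per image), or
mixed pixels at boundaries. Results on real data depend on those.

## Numerical conventions

* Strict `>` at every threshold; values exactly at a threshold are
  background.
* `0/0`-type index denominators are defined case by case (green index 0,
  NDVI 0, stem ratio: stem only if the numerator is positive).
* Residual sums of squares at or below 1e-12 are treated as numerical
  zero in the error-fraction denominators (saturated fits leave
  float-noise residuals).
* 8-bit quantization rounds half up after min-max rescaling.
* Every random draw derives from one master seed plus fixed tags per
  object (design block, trait panel, leaf geometry, illumination), so
  any single scene can be re-rendered independently and identically.

## Command-line use

`inst/scripts/phenomap` wraps the two entry points a shell user needs:
`simulate` (write a synthetic experiment tree) and `run` (index a tree,
extract all traits, and write `traits.csv`, `fluor.csv`,
`hyper_counts.csv`, `spectra.csv`, `h2.csv`, `biomass.json`, and a
`MANIFEST.txt` of per-stage completion). All stages are deterministic
given the seeds, and reruns produce byte-identical CSV outputs.
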