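---
title: "Methods: rainfall variability, fire and tree-grass cover in grassy biomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rainfall variability, fire and tree-grass cover in grassy biomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgbcover)
```

## The scientific question and the modelling approach

Tropical grassy biomes (TGBs) — savannas and grasslands with a continuous
C4 grass layer — respond to rainfall not only through its annual total but
through *how* the rain arrives: how strongly it is concentrated in a wet
season, and, within that season, how frequent and how intense the daily
events are. This package implements a per-grid-cell analysis of fractional
tree cover T and grass cover G against five abiotic drivers: mean annual
rainfall (MAR, mm y⁻¹), the Walsh–Lawler seasonality index (SI), wet-season
daily rainfall frequency (λ_w, d⁻¹) and intensity (α_w, mm d⁻¹), and the
log average fire interval log₁₀(AFI). Because the dominant mechanisms
change along the rainfall gradient, the analysis is run separately in three
MAR ranges — R1 (MAR ≤ 630), R2 (630 < MAR < 1200) and R3
(1200 ≤ MAR ≤ 2500 mm y⁻¹) — as well as pooled.

## Rainfall descriptors

All rainfall metrics derive from a complete multi-year daily series on a
365-day civil calendar (no leap days; at the precision of these metrics a
leap day is irrelevant, and a fixed-length year keeps every (year, day)
index complete).

* **Monthly climatology and MAR.** Each calendar month's total is averaged
  over years; MAR is the mean annual total.
* **Seasonality.** SI = (1/R) Σₘ |xₘ − R/12| with R the annual mean and xₘ
  the climatological monthly totals. SI is 0 for uniform rain and 22/12 ≈
  1.83 when all rain falls in one month. SI is undefined for a zero annual
  total and the package raises a typed error rather than returning a value.
* **Wet season.** A month is wet when its climatological rainfall strictly
  exceeds `p_thr` × (R/12). The default `p_thr = 0.5` is the value at which
  the detected season length L_w correlates best with the threshold-free
  length implied by seasonality, L_w,SI = 365/12·[11(1 − SI/1.83) + 1];
  `calibrate_pthr()` reproduces that calibration on any cell collection.
  Ties at the threshold count as dry (a literal reading of "greater than"),
  and wet months need not be contiguous, so bimodal rainfall regimes are
  representable. The constant 1.83 is used exactly as printed in the field's
  convention, not the exact bound 22/12; the difference is below 0.2%.
* **Intensity, frequency and the water balance.** Within wet-season months,
  a *wet day* has depth > 0.1 mm d⁻¹ (a guard against measurement noise).
  α_w is the pooled mean depth over wet days; λ_w is the average annual
  number of wet days divided by the climatological L_w. With
  c = MAR_w − α_w·λ_w·L_w (the annual sub-threshold rain inside the wet
  season), the identity MAR_w = α_w·λ_w·L_w + c holds exactly by
  construction; the test suite checks it to 1e−6 relative on every
  simulated cell. When no day exceeds the threshold α_w is undefined and
  returned as `NA` with a warning, λ_w = 0 and c absorbs all of MAR_w.

A design point worth making explicit: λ_w divides by the *climatological*
L_w (one wet-month set per cell), not by per-year season lengths. This
matches the definition of a frequency per average wet-season day and keeps
the water balance exact with a single L_w per cell.

## Fire metrics

The average fire interval is AFI = 1/(BA + ε) with BA the mean annual
burnt-area fraction and ε = 0.0001 y⁻¹, capping unburnt cells at 10,000 y
instead of infinity; the analysis uses log₁₀(AFI) because intervals span
orders of magnitude. Within a year, monthly burnt fractions are summed and
clipped at 1, so a patch that burns twice in a year counts once — a
deliberate simplification of re-burn bookkeeping.

## Cell filtering

Cells are dropped when shrubland exceeds 50% of the area (tree-cover
products under-read under shrub), or when the combined human-influenced,
water and permanent snow/ice fraction exceeds 1/3. The 1/3 rule is applied
to the *union* of those classes — the conservative reading of a mask that
lists them jointly; per-class thresholds are configurable. TGB cells are
those with a strict majority of deciduous trees + grassland, and cells with
MAR > 2500 mm y⁻¹ are excluded. Boundary conventions are R1 closed above at
630 and R3 closed below at 1200. Per-range distributions are compared with
two-sided Wilcoxon rank-sum tests (`stats::wilcox.test`).

## Cover models and selection

T and G are fractions in [0, 1], so they are modelled with a binomial error
distribution and logit link. A likelihood (and hence AIC) needs a binomial
denominator; the package treats each cell's fraction as a count out of
`n_trials = 100` — percent-cover resolution, consistent with the generator.
Absolute AIC values depend on this choice, AIC *rankings* only weakly so;
comparisons should stay within one `n_trials`.

Predictors are standardized (mean 0, sample n−1 SD 1) so coefficient
magnitudes are comparable importance measures; the transform is retained so
fitted features (e.g. a parabola vertex) can be mapped back to natural
units via mean + sd·z.

The candidate set per response contains: nested polynomials of each single
predictor up to cubic (a quadratic model always includes the linear term —
the hierarchical convention that also makes the count come out right),
every ≥2-predictor linear combination except those containing both α_w and
λ_w (the two are linked through the water balance, so joint inclusion is
uninterpretable), and the intercept-only model: 15 + 18 + 1 = 34 models.
They are ranked by AIC (ties broken toward fewer terms, then label order);
models with AIC below the intercept-only model are flagged `retained`, and
goodness of fit is the explained deviance R² = 1 − D_m/D_0. Fitting is
iteratively reweighted least squares via `stats::glm`; the test suite
cross-checks the coefficients against an independent BFGS maximizer of the
binomial log-likelihood to 1e−6.

One property of AIC matters for interpreting the package's own selection
simulations: AIC is not selection-consistent. Even with overwhelming
signal, a spurious extra predictor improves AIC whenever its likelihood-
ratio statistic exceeds 2, which happens with probability ≈ 0.157 under the
null. With two free predictors available to extend a true two-term model,
the exact generating term set is the single best model in only ≈ 70% of
replicates, the remainder going to strict supersets. Recovery of the
generating *coefficients* is unaffected.

## Residual analysis of collinearity

Wherever a best model contains α_w or λ_w, the package asks whether that
influence is direct: both the cover response (binomial-logit) and the
intra-seasonal variable are regressed on MAR, SI and log₁₀(AFI), and the
squared correlation of the two deviance-residual vectors is reported. The
family for the predictor-side model is not dictated by the procedure; the
package uses a normal-identity model (ordinary least squares), the simplest
GLM for a continuous positive variable at these scales, for which deviance
residuals are raw residuals; the term structure is configurable. The
statistic is invariant to affine rescaling of the intra-seasonal variable,
concentrates near zero under the no-direct-effect null (even with strong
collinearity between λ_w and MAR) and grows with an injected direct effect
— both behaviours are exercised in the tests at n = 694 cells.

## The synthetic-data generator

The generator exists so that every stage is testable without satellite
downloads; its defaults encode the study conditions the pipeline targets.

* **Daily rainfall** is marked-Bernoulli: wet-season days rain with
  probability `event_prob` and exponential depths of mean `mean_depth`
  (single-parameter, matching the mean-intensity definition of α_w; a
  gamma law would add a shape parameter the metrics never see). Dry-season
  drizzle (probability 0.05, mean 0.5 mm d⁻¹) exercises the wet-day
  threshold and the closing term c without materially moving MAR.
* **The default study** has 694/783/215 surviving cells in R1/R2/R3 (1692
  in total) plus 40 cells destined for the masks, 11 years of daily data
  per cell and 100 binomial trials per cover draw. Per-range regimes (3–5,
  5–7, 7–9 contiguous wet months; event frequencies 0.25–0.5, 0.3–0.7,
  0.45–0.8 d⁻¹; log₁₀ AFI 0.5–3, 0–1.5, 0.5–2.5) are chosen once to sit in
  the ranges typical of dry, mesic and humid African TGBs. Target MAR is
  drawn uniformly *within* each range but away from the boundaries, and
  event intensity is capped per range (12/12/15 mm d⁻¹, with frequency
  compensating), so that the realized MAR — an 11-year average with
  sampling noise — classifies every cell into its intended range and the
  surviving per-range counts equal the configured ones.
* **Cover** is drawn per cell as Binomial(n_trials, logistic(η))/n_trials,
  with η a linear/quadratic form over within-range standardized predictors.
  The default generating models are the per-range best fits this kind of
  analysis reports: dry-range tree cover rising with MAR
  (−3.85 + 0.55·MAR), dry-range grass driven by SI and λ_w, mesic tree
  cover parabolic in λ_w, mesic grass declining with fire interval and
  λ_w, and humid tree cover declining with α_w. No supported model exists
  for humid grass cover, so it is generated intercept-only at logit −0.2
  (≈ 45% grass, a plausible humid-TGB level).
* **Land cover** mixes archetypes with deterministic (largest-remainder)
  counts, so accepted and rejected cells for every filtering rule are
  guaranteed by construction, and grassy-biome cells are built to stay
  below the mask thresholds.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: spatial autocorrelation of rainfall and fire
(cells are independent), orographic structure, sub-daily rainfall, the
empirical joint distribution of predictors (only the marginals are matched
qualitatively, so real-world collinearity such as the λ_w–MAR correlation
appears only where a test injects it), observation error in cover, and
overdispersion relative to the binomial (real percent-cover data is noisier
than Binomial(100)). Tree and grass fractions are drawn independently, so
T + G can exceed 1 in a way real vegetation continuous fields would not.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviations throughout; standardizing affects
  coefficient scale, never fit quality.
* `glm` runs with up to 100 IRLS iterations: near-saturated fits at very
  large binomial denominators can oscillate at the deviance rounding floor
  under the default iteration cap.
* Complete years are enforced on input; incomplete records are an error,
  not silently padded.
* Zero-rainfall cells: SI errors, wet season is empty with a warning,
  metrics return `NA`/0 flags rather than fabricated values.
* Perfect separation in a cover fit is flagged on the fit object, not
  silently ignored; non-convergence is a typed error.
* A parabola extremum requires a genuinely quadratic single-predictor fit;
  a zero quadratic coefficient is a typed error, and a zero linear term
  puts the vertex at the predictor mean.

## Problem sizes

The test suite runs reduced configurations chosen to exercise every code
path at interactive speed: the full 1692-cell, 11-year study for count
invariants is replaced in most tests by an identically structured
210-cell, 6-year scenario; water-balance and distribution checks use a
1000-cell grid; parameter-recovery and residual-analysis simulations use
the per-range sample sizes (694 and 215 cells) with 100–200 seeds. The
acceptance script reports the seasonality closed form (12 months) and the
on-average recovered slope at 694 cells over 200 seeds.

## Known limitations

Beyond the generator's scope notes above: the pipeline consumes per-cell
tables, not native satellite rasters (regridding, quality flags and tile
decoding are out of scope); AIC values are comparable only within a fixed
binomial denominator; and the residual analysis quantifies association, not
causal mediation — a high residual R² says the intra-seasonal variable
carries signal beyond MAR, SI and fire, not why.
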