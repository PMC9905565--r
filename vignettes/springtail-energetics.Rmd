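---
title: "From soil samples to global energetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From soil samples to global energetics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springtailMetrics)
```

This vignette documents the scientific models implemented in
`springtailMetrics`, the parameters that matter, and the design decisions
taken where conventions in the literature are ambiguous. It is the
reference companion to the function documentation.

## The pipeline at a glance

Soil springtail (Collembola) surveys produce per-sample taxon abundance
tables: a site is visited, a handful of soil cores of known area are
extracted (typically by Tullgren/Berlese funnels), and individuals are
counted per taxon. The pipeline converts these into site-level metrics in
five steps: (1) ingestion and taxon-name harmonization, (2) trait
attachment, (3) allometric mass and metabolic-rate estimation,
(4) aggregation to site metrics, and (5) scaling to latitudinal belts and
gridded global totals.

## Ingestion and harmonization

Field datasets carry typos and synonyms. `harmonizeTaxon()` matches names
against a packaged genus checklist by case-insensitive Levenshtein
distance, with a default maximum accepted distance of 2. The threshold is a
compromise: distance 1 misses transposed digraphs, while distance 3 starts
conflating genuinely distinct genus names (many collembolan genera differ
by few characters, e.g. *Isotoma*/*Isotomurus* share a long prefix).
Matching is deterministic: smallest distance wins, ties break
alphabetically. The genus is the first whitespace-delimited token of the
matched name; records that cannot be identified to genus are excluded from
mass and metabolism (not from density), because traits are attached at the
genus level.

Climate bands partition latitude at the polar circles and tropics:
`|lat| > 66.5` is polar, `|lat| ≤ 23.5` tropical, temperate in between.
Boundaries are closed on the equatorward side (exactly 66.5 → temperate,
exactly 23.5 → tropical), consistent with "beyond the polar circles" and
"in between the tropics" readings. Ecosystem types are the band × habitat
pairs; nine types (three polar, four temperate, tropical woodland and
tropical agriculture) are treated as well-represented and flagged
`retained` for cross-type comparisons.

## Allometry and metabolism

**Length to mass.** Dry mass (µg) comes from genus mean body length (mm)
via group-specific regressions on the log10–log10 scale,
`log10(m) = intercept + slope · log10(L)`. When several regressions cover a
morphogroup, their back-transformed predictions are averaged
arithmetically. The packaged coefficient table
(`inst/extdata/allometry_synthetic.tsv`) carries synthetic values of
realistic magnitude — the file format accepts published supplementary
coefficients as a drop-in replacement. Fresh mass is dry mass times a
group conversion factor; factors near `1/(1 − 0.70) ≈ 3.33` correspond to
the ~70 % body-water content of springtails, and the class validity check
requires factors > 1.

**Coefficient uncertainty.** The `variant` argument propagates regression
uncertainty: `"max"`/`"min"` evaluate each regression at the upper/lower
envelope of its ±1 SE coefficient box, i.e.
`intercept ± SE` plus `± slope_se·|log10 L|` on the slope term. The
envelope formulation (rather than literally adding the SE to the slope) is
deliberate: for animals shorter than 1 mm, `log10 L` is negative, so a
raised slope *lowers* the predicted mass and a naive shift would break the
ordering min ≤ mean ≤ max that any uncertainty band must satisfy. The
envelope is the pointwise extremum of the regression line over the
coefficient box and preserves the ordering for every length.

**Metabolic rate.** Individual rate follows the Boltzmann–Arrhenius model
with the insect coefficient set: `ln i0 = 21.972` (J h⁻¹ scale),
`a = 0.759`, `E = 0.657 eV`, `k = 8.617e−5 eV K⁻¹`. The mass unit in this
coefficient set is **mg fresh mass**; this is easy to get wrong, and the
package treats it as a hard convention (`individualMetabolicRate()` takes
mg). A site-mean rate computed with grams would fall orders of magnitude
below the plausible 0.028–2.4 mJ h⁻¹ range for springtail communities,
which is the sanity check used in the tests. Temperature is mean annual
topsoil (0–5 cm) temperature converted as `T[K] = °C + 273.15`. Using an
annual mean assumes the seasonal activity window is represented by the
annual average; this understates seasonal dynamics but keeps sites
comparable.

**Site aggregation.** Density is the across-sample mean of
(total individuals / sampling area). Biomass and community metabolism sum
per-individual masses/rates within a sample, divide by the sample area, and
average across samples. Community-weighted mean (CWM) body mass and
individual rate are abundance-weighted means per sample, then averaged
across the site's samples with a symmetric 10 % trim. Trimming at the
sample level (rather than over pooled specimens) is the default because
outlier *samples* — a funnel that failed, a core that hit an ant nest — are
the dominant error mode; specimen-level trimming is available via
`trim_level = "specimen"`. The trim count is `floor(n · trim)` per tail
with a stable sort, so nothing is dropped when fewer than `1/trim` values
exist.

**Energy to carbon.** `energyToCarbon()` converts J to kg C via
7×10⁶ J per kg fresh mass, 70 % water, 45 % C of dry mass; the chain is
linear and `7e6 J → 0.135 kg C`. Monthly totals use 730.5 h per month.

## Richness

Sample-based rarefaction uses the exact hypergeometric expectation, so no
resampling noise enters the curve. Extrapolated richness uses the
incidence-based Chao estimator with the small-sample correction,
`S_obs + ((m−1)/m)·Q1(Q1−1)/(2(Q2+1))`. The `(Q2+1)` denominator makes the
estimator defined when doubletons are absent without special-casing, and
the estimate can never fall below `S_obs`. The classic uncorrected form and
an abundance-based Chao1 are provided but not default; the sample-based
variant matches data collected as discrete soil cores. Extrapolations from
sites with fewer than 3 samples are suppressed (`NA`), because
singleton/doubleton counts from one or two cores are dominated by noise.

Sites reported only as pooled species lists are corrected through the
completeness model: a logit-link GLM of completeness (observed/Chao ratio)
on `n_samples * latitude`, fitted by quasi-binomial likelihood on sites
with ≥ 5 samples (continuous proportions with unit weights), with
per-term sequential likelihood-ratio statistics as in
`anova(fit, test = "Chisq")`. Pooled richness is then
`S_obs / predicted completeness`; the logit link keeps the prediction in
(0, 1), and predictions below 0.1 (a more than 10-fold correction) are
flagged rather than trusted.

## Quality control

The three layer-protocol rules exclude estimation regimes known to
undercount: woodlands sampled as a single layer (litter-only misses
soil-dwellers and vice versa), scrub sampled as ground cover only, and
shallow (< 10 cm) soil-only sampling in temperate agriculture. Rules are
evaluated independently and exclusion is their union, so the result is
order-independent; sites without layer metadata are flagged `unevaluated`
instead of being silently retained or dropped.

Low-density outliers are *flagged*, not removed: a site must be both in the
lowest decile of its ecosystem type and below one third of the type's 1st
percentile. The percentile uses the type-7 (linear interpolation) quantile —
the R default — computed on the raw scale; for a fixed quantile definition
the rule is equivariant to monotone rescaling, so the raw/log choice is
immaterial. Exclusion requires the site to appear on an explicit deny list,
mirroring a manual-inspection step while keeping the decision reproducible;
an allow list overrides. Ecosystem types with fewer than 20 sites yield no
flags (the 1st percentile is not estimable) and a warning.

## Latitudinal belts and summaries

Belt averages use fixed 5-degree bins with edges at multiples of 5,
half-open `[lo, hi)`, so a site at exactly 25° falls in [25, 30). Skewed
metrics (density, biomass, metabolism) are averaged on the log10 scale with
a 10 % trim per belt — the same trimming convention as site aggregation —
and back-transformed; this gives each belt the same statistical weight
regardless of site count. `log10Metric()` rejects zeros rather than adding
pseudo-counts: a zero density is a data problem to resolve upstream.

## Geospatial ensemble

The mapping module trains a grid of 18 random-forest configurations
(variables per split 2–7 × minimum leaf population 3–5), scores each by
10-fold cross-validated R² (folds assigned randomly from the seed,
identical across configurations), and predicts each grid pixel as the
unweighted mean of the 10 best configurations refitted on all data.
Selection uses the mean out-of-fold R² per configuration — the natural
summary when folds are random rather than spatial. The regression engine is
pluggable (`ranger` by default, `lm` for linear simulations) because the
module's contribution is the CV/ensemble/masking logic, not the learner.

Responses are modelled on the log10 scale and back-transformed with `10^x`
without a smearing correction; the bias of that choice is small relative to
prediction error at these problem sizes but real (the exponential of an
unbiased log prediction is biased), and the acceptance script's
estimated/true total ratio quantifies it rather than hiding it.

**Extrapolation mask.** Training covariates are transformed by centred,
scaled PCA; the leading axes jointly explaining ≥ 90 % of variance are
retained (the axis count follows the variance target, not a fixed number);
convex hulls are drawn around the training scores in every bivariate axis
pair; a pixel's outside-fraction is the share of axis pairs whose hull
excludes it, and pixels above 0.90 are masked. Hulls are closed (boundary
points count as inside), implemented by a cross-product orientation test —
a point exactly on an edge of the training envelope is not an
extrapolation.

**Uncertainty.** The stratified bootstrap resamples sites with replacement
with per-region draw counts apportioned (largest remainder) to each
region's relative land area, so spatial sampling bias does not propagate
into the uncertainty estimate. Each of the 100 resamples refits the model
and predicts the grid; maps are reduced pixelwise to mean, SD, empirical
2.5/97.5 percentile interval, and coefficient of variation. The region
areas should be the *actual* relative areas of the strata; with a synthetic
globe they are computed from the grid's own pixel areas. Pixel areas use
the spherical formula `R²·Δλ·(sin φ₂ − sin φ₁)` with R = 6,371,000 m, and
global totals are `Σ value × area` over unmasked pixels. Residual spatial
structure is diagnosed with Moran's I under binary great-circle
distance-band weights (150 km default).

Every stochastic operation takes an explicit seed and is bit-reproducible.

## The synthetic-data generator

The generator's defaults encode the study conditions the package is tested
under, chosen once: log10 density rising at `log10(20)/70` per degree of
absolute latitude from 10^3.78 ≈ 6000 individuals m⁻² at the equator (a
20-fold polar:tropical gradient with between-site SD 0.4 log10 units);
topsoil temperature falling linearly from 27 °C at the equator to −10 °C at
70°; Poisson(6) samples per site truncated to 1–20 (median 6); 5 × 5 cm
cores; negative-binomial per-sample counts (size 2) over a site genus pool
drawn with lognormal relative-abundance weights from the packaged 0.2–5 mm
trait table; and habitat mixtures per climate band that populate all nine
retained ecosystem types. Under these conditions the energy-equivalence
pattern is an emergent property, not an assertion: the Arrhenius factor
between −10 °C and 27 °C is ≈ 35-fold at equal mass, which offsets the
20-fold biomass gradient to within a ~2–3-fold band of community
metabolism across belts.

What the generator does **not** emulate: real taxonomic composition and
its latitudinal turnover (genus pools are random draws, body size is
latitude-independent), spatial clustering of sites within regions,
seasonal sampling windows, method heterogeneity, and the long tail of data
entry errors. Passing tests therefore demonstrate that the estimators and
the scaling machinery are correct and internally consistent under
realistic magnitudes — not that the package reproduces any particular
field dataset.

## Problem sizes

The test suite and acceptance script run at deliberately chosen sizes: the
headline-pattern and slope-recovery checks use 2000 synthetic sites
(matching the ~10³-site scale of global compilations; at a few hundred
sites the 5-degree belt means are dominated by sampling noise), the
synthetic globe is 30 × 15 pixels with 200 training sites, completeness-GLM
recovery uses 100 replicates of 500 sites, and bootstrap coverage uses 100
replicated experiments of 100 resamples each.

## Known limitations

* Genus-level mean body lengths ignore within-genus and latitudinal size
  variation; the coefficient variants bound regression uncertainty, not
  trait uncertainty.
* The completeness GLM treats continuous proportions as quasi-binomial;
  completeness values of exactly 1 carry less information than their
  weight implies when many sites are fully sampled.
* Back-transformed ensemble predictions are median-scale, not mean-scale;
  totals inherit a small negative-to-positive bias depending on prediction
  variance (smearing is deliberately not applied by default).
* The packaged allometry and trait tables are synthetic placeholders of
  realistic magnitude, clearly labelled; quantitative results on real data
  require the published coefficient tables in the same file format.
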