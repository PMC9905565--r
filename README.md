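# springtailMetrics

Springtails (Collembola) are among the most abundant soil animals on Earth,
and their community-level density, biomass and energy use are key metrics of
soil functioning. Estimating those metrics from heterogeneous field surveys
is laborious: raw data arrive as per-sample taxon abundance tables with
varying sampling areas, layers and identification depth, and body masses are
rarely measured directly. `springtailMetrics` packages the full trait-based
pipeline for soil ecologists and macroecologists who need to turn such
tables into comparable site-level metrics and scale them up:

* **ingest & harmonization** — delimited-table reading with row-level
  validation, Levenshtein matching of taxon names against a packaged genus
  checklist, climate-band and ecosystem-type classification;
* **allometry & metabolism** — genus body lengths to dry/fresh mass via
  group-specific log10–log10 regressions, individual metabolic rates from
  the metabolic theory of ecology, site-level aggregation with trimmed
  community-weighted means and coefficient-uncertainty propagation;
* **richness** — analytic sample-based rarefaction, incidence-based Chao
  extrapolation, and a completeness GLM to correct sites with only pooled
  species lists;
* **quality control** — the documented layer-protocol exclusion rules and
  low-density outlier flagging;
* **gradients** — 5-degree latitudinal belt averages and ecosystem-type
  summaries;
* **geospatial ensemble** — an 18-configuration random-forest grid scored by
  10-fold cross validation, a top-10 ensemble, convex-hull extrapolation
  masking in principal-component space, spatially stratified bootstrap
  uncertainty, and global totals in carbon units;
* **synthetic data** — a generator with known ground truth so every stage is
  testable offline.

## The core model

Individual metabolic rate follows the Boltzmann–Arrhenius form of the
metabolic theory of ecology,

    I = exp( ln i0 + a·ln M − E/(k·T) )   [J h⁻¹]

with fresh body mass `M` in mg, normalization `ln i0 = 21.972`, allometric
exponent `a = 0.759`, activation energy `E = 0.657 eV`, Boltzmann constant
`k = 8.617e−5 eV K⁻¹`, and `T` the mean annual topsoil temperature in K.
Body mass comes from genus-level body length `L` (mm) via group-specific
regressions `log10(m) = intercept + slope·log10(L)` (averaged when several
regressions cover a morphogroup) and a dry-to-fresh conversion factor.
Community metabolism is the per-area sum of individual rates; energy totals
convert to carbon assuming 7×10⁶ J per kg fresh mass, 70 % body water and
45 % carbon in dry mass. Site richness is extrapolated with the
incidence-based Chao estimator
`S = S_obs + ((m−1)/m)·Q1(Q1−1)/(2(Q2+1))`.

## Worked example

```r
library(springtailMetrics)
f  <- system.file("extdata", "community_example.csv", package = "springtailMetrics")
cd <- attachTraits(readCommunityTable(f, quiet = TRUE))
cd
#> CommunityData: 13 sample x taxon rows, 7 samples, 3 sites
#>   habitats: scrub:1 woodland:2

computeSiteMetrics(cd)[, c("site_id", "density", "dry_biomass_mg_m2",
                           "mean_individual_metabolism_mJ_h",
                           "community_metabolism_J_h_m2", "ecosystem_type")]
#>   site_id density dry_biomass_mg_m2 mean_individual_metabolism_mJ_h
#> 1    BR01    1200              12.3                           2.760
#> 2    DE01   11200              65.0                           0.274
#> 3    NO01  129500             803.4                           0.141
#>   community_metabolism_J_h_m2     ecosystem_type
#> 1                        2.51  tropical_woodland
#> 2                        3.22 temperate_woodland
#> 3                       18.57        polar_scrub
```

The three sites illustrate the pattern the pipeline is built to quantify:
the tundra site (NO01) holds two orders of magnitude more individuals and
~65× more biomass than the tropical site (BR01), but because individual
metabolic rates are ~20× higher in the warm tropics, community metabolism
differs far less (2.5 vs 18.6 J h⁻¹ m⁻²) than biomass does. Richness
extrapolation reports the Chao estimate and sampling completeness, and
suppresses estimates for sites with fewer than three samples:

```r
siteRichness(cd)
#>   site_id n_samples S_obs S_chao completeness
#> 1    DE01         3     5      7        0.714
#> 2    NO01         2     3     NA           NA
#> 3    BR01         2     3     NA           NA
```

Single-quantity helpers work the same way, e.g. the metabolic rate of a
0.01 mg animal at 10 °C:

```r
individualMetabolicRate(0.01, 283.15)
#> [1] 0.000214   # J/h, i.e. 0.21 mJ/h
```

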