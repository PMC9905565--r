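test_that("length-mass regression evaluates and averages as specified", {
  # identity coefficients: log10(m) = 0 + 3*log10(1) -> mass 1
  a1 <- allometrySet(data.frame(group = "g", intercept = 0, intercept_se = 0,
                                slope = 3, slope_se = 0,
                                dry_fresh_factor = 3, dry_fresh_se = 0))
  expect_equal(lengthToDryMass(1, "g", a1), 1)
  # two regressions giving 8 and 12 -> 10
  a2 <- allometrySet(data.frame(
    group = "g", intercept = log10(c(8, 12)), intercept_se = 0,
    slope = 2, slope_se = 0, dry_fresh_factor = 3, dry_fresh_se = 0))
  expect_equal(lengthToDryMass(1, "g", a2), 10)
  # shifted-intercept variant evaluated by hand: a = 2.0 (SE 0.5), b = 2.5,
  # L = 2 mm, max -> 10^(2.5 + 2.5*log10(2))
  a3 <- allometrySet(data.frame(group = "g", intercept = 2.0,
                                intercept_se = 0.5, slope = 2.5,
                                slope_se = 0, dry_fresh_factor = 3,
                                dry_fresh_se = 0))
  expect_equal(lengthToDryMass(2, "g", a3, variant = "max"),
               10^(2.5 + 2.5 * log10(2)))
  expect_error(lengthToDryMass(1, "nope", a1), "nope")
})

test_that("dry-to-fresh conversion is multiplicative and validated", {
  a <- toyAllometry()
  expect_equal(dryToFreshMass(0, "g", a), 0)
  # factor 10/3 is consistent with 70% body water: fresh = dry/(1 - 0.70)
  expect_equal(dryToFreshMass(3, "g", a), 10)
  expect_error(allometrySet(data.frame(
    group = "g", intercept = 0, intercept_se = 0, slope = 2, slope_se = 0,
    dry_fresh_factor = 1, dry_fresh_se = 0)), "dry_fresh_factor")
})

test_that("metabolic rate follows the Boltzmann-Arrhenius power law", {
  cst <- metabolicConstants()
  # independent hand evaluation of the stated equation
  hand <- exp(21.972 + 0.759 * log(0.01) - 0.657 / (8.617e-5 * 283.15))
  expect_equal(individualMetabolicRate(0.01, 283.15), hand,
               tolerance = 1e-12)
  # doubling mass multiplies rate by exactly 2^0.759
  m <- runif(50, 0.001, 3)
  expect_equal(individualMetabolicRate(2 * m, 290),
               individualMetabolicRate(m, 290) * 2^0.759)
  # strictly increasing in both arguments
  expect_true(all(diff(individualMetabolicRate(seq(0.01, 1, 0.01), 280)) > 0))
  expect_true(all(diff(individualMetabolicRate(0.05, seq(260, 310, 1))) > 0))
  expect_error(individualMetabolicRate(-1, 280), "fresh_mass_mg")
})

test_that("trimmed mean matches brute-force enumeration", {
  expect_equal(trimmedMean(c(5, 5, 5, 5), 0.10), 5)
  expect_equal(trimmedMean(1:10, 0.10), mean(2:9))
  expect_equal(trimmedMean(c(3, 1, 7), 0), mean(c(3, 1, 7)))
  set.seed(42)
  for (i in 1:50) {
    x <- rlnorm(sample(3:40, 1))
    tr <- sample(c(0, 0.05, 0.1, 0.25, 0.4), 1)
    expect_equal(trimmedMean(x, tr), bruteTrimmedMean(x, tr))
  }
  expect_error(trimmedMean(numeric(0)), "no data")
})

test_that("energy-to-carbon conversion is the stated linear chain", {
  expect_equal(energyToCarbon(7e6), 0.135)
  expect_equal(energyToCarbon(0), 0)
  x <- runif(10, 0, 1e8)
  expect_equal(energyToCarbon(2 * x), 2 * energyToCarbon(x))
})

test_that("site metrics match direct arithmetic on toy cases", {
  # one sample, 10 individuals, area 0.01 -> density 1000
  s <- data.frame(site_id = "a", sample_id = "a1", taxon = "Folsomia",
                  abundance = 10, sampling_area = 0.01, sampling_depth = 5,
                  layers = "soil", method = "t")
  st <- data.frame(site_id = "a", latitude = 50, longitude = 8,
                   habitat = "woodland", soil_temperature = 10)
  m <- computeSiteMetrics(attachTraits(communityData(s, st)))
  expect_equal(m$density, 1000)
  # two samples with per-sample densities 1000 and 3000 -> 2000
  s2 <- rbind(s, within(s, {sample_id <- "a2"; abundance <- 30}))
  m2 <- computeSiteMetrics(attachTraits(communityData(s2, st)))
  expect_equal(m2$density, 2000)
})

test_that("vectorized site metrics equal the per-specimen loop oracle", {
  set.seed(7)
  gd <- generateDataset(generatorConfig(n_sites = 6, seed = 21))
  cd <- attachTraits(gd$data)
  metrics <- computeSiteMetrics(cd)
  s <- communitySamples(cd)
  s$dry_ug <- lengthToDryMass(s$body_length_mm, s$morphogroup)
  for (id in metrics$site_id) {
    ss <- s[s$site_id == id, ]
    oracle <- bruteSiteSums(ss, "dry_ug") / 1000
    expect_equal(metrics$dry_biomass_mg_m2[metrics$site_id == id], oracle,
                 tolerance = 1e-9)
  }
})

test_that("sites without genus-level traits keep density only, with reason", {
  s <- data.frame(site_id = "a", sample_id = "a1", taxon = "Unknownus",
                  abundance = 10, sampling_area = 0.01, sampling_depth = 5,
                  layers = "soil", method = "t")
  st <- data.frame(site_id = "a", latitude = 50, longitude = 8,
                   habitat = "woodland", soil_temperature = 10)
  m <- computeSiteMetrics(attachTraits(communityData(s, st),
                                       max_distance = 0))
  expect_equal(m$density, 1000)
  expect_true(is.na(m$dry_biomass_mg_m2))
  expect_match(m$note, "no genus-level traits")
})

test_that("fresh/dry biomass ratio equals the group conversion factor", {
  cd <- toyCommunity()
  # restrict to one morphogroup so the expected ratio is a single factor
  s <- communitySamples(cd)
  s <- s[s$morphogroup == "entomobryomorpha", ]
  cd1 <- communityData(s, siteTable(cd))
  m <- computeSiteMetrics(cd1)
  tb <- allometryTable(defaultAllometry())
  f <- mean(tb$dry_fresh_factor[tb$group == "entomobryomorpha"])
  expect_equal(m$fresh_biomass_mg_m2 / m$dry_biomass_mg_m2, f)
})

test_that("coefficient variants order min <= mean <= max pointwise", {
  a <- defaultAllometry()
  set.seed(3)
  L <- runif(200, 0.2, 5)   # includes lengths below 1 mm
  g <- sample(allometryGroups(a), 200, replace = TRUE)
  lo <- lengthToDryMass(L, g, a, "min")
  mid <- lengthToDryMass(L, g, a, "mean")
  hi <- lengthToDryMass(L, g, a, "max")
  expect_true(all(lo <= mid & mid <= hi))
  expect_true(all(dryToFreshMass(mid, g, a, "min") <=
                    dryToFreshMass(mid, g, a, "max")))
})
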