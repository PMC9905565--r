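mkSite <- function(id, habitat, lat, layers, depth = 5) {
  list(samples = data.frame(site_id = id, sample_id = paste0(id, "_1"),
                            taxon = "Folsomia", abundance = 5,
                            sampling_area = 0.01, sampling_depth = depth,
                            layers = layers, method = "t"),
       sites = data.frame(site_id = id, latitude = lat, longitude = 0,
                          habitat = habitat, soil_temperature = 8))
}

qcFixture <- function() {
  parts <- list(
    mkSite("w_litter", "woodland", 50, "litter"),
    mkSite("w_both", "woodland", 50, "litter+soil"),
    mkSite("s_cover", "scrub", 68, "litter+other_cover"),
    mkSite("agri_shallow", "agriculture", 45, "soil", depth = 8),
    mkSite("agri_deep", "agriculture", 45, "soil", depth = 20),
    mkSite("no_layers", "grassland", 45, NA))
  communityData(do.call(rbind, lapply(parts, `[[`, "samples")),
                do.call(rbind, lapply(parts, `[[`, "sites")))
}

test_that("layer rules exclude the documented protocols and only those", {
  rep <- applyLayerRules(qcFixture())
  get <- function(id, col) rep[[col]][rep$site_id == id]
  expect_true(get("w_litter", "rule1_woodland_single_layer"))
  expect_true(get("w_litter", "excluded"))
  expect_false(get("w_both", "excluded"))
  expect_true(get("s_cover", "rule2_scrub_cover_only"))
  expect_true(get("agri_shallow", "rule3_temperate_agri_shallow"))
  expect_false(get("agri_deep", "excluded"))
  expect_true(get("no_layers", "unevaluated"))
  expect_false(get("no_layers", "excluded"))
})

test_that("low-density outliers need both the decile and the percentile/3 rule", {
  set.seed(23)
  # 1% percentile sits at the 3rd/4th order statistics (both 900), so the
  # rule threshold is 900/3 = 300: the 250 site is flagged, the 400 is not
  dens <- c(250, 400, 900, 900, runif(296, 1000, 50000))
  met <- data.frame(site_id = sprintf("s%03d", seq_along(dens)),
                    density = dens,
                    ecosystem_type = "temperate_woodland")
  q01 <- quantile(met$density, 0.01, type = 7, names = FALSE)
  expect_equal(q01, 900)
  fl <- flagLowDensityOutliers(met)
  flagged <- fl$site_id[fl$flagged]
  expect_true(all(fl$density[fl$flagged] < q01 / 3))
  expect_true("s001" %in% flagged)   # 250 < 300
  expect_false("s002" %in% flagged)  # 400 > 300
  # degenerate distribution: no flags
  met2 <- data.frame(site_id = sprintf("x%02d", 1:30), density = 5000,
                     ecosystem_type = "polar_scrub")
  expect_false(any(flagLowDensityOutliers(met2)$flagged))
  # too few sites: warning and no flags
  met3 <- data.frame(site_id = c("a", "b"), density = c(1, 1e6),
                     ecosystem_type = "tropical_woodland")
  expect_warning(fl3 <- flagLowDensityOutliers(met3), "no outlier flags")
  expect_false(any(fl3$flagged))
})

test_that("richness eligibility needs 3 samples and species-level IDs", {
  sites <- data.frame(site_id = c("a", "b", "c"),
                      n_samples = c(2, 6, 6),
                      id_level = c("species", "species", "genus"))
  el <- richnessEligibility(sites)
  expect_equal(el$richness_eligible, c(FALSE, TRUE, FALSE))
})

test_that("filters are order-independent and the report reconciles", {
  cd <- qcFixture()
  met <- data.frame(site_id = siteTable(cd)$site_id,
                    density = c(100, 5000, 8000, 3000, 4000, 2000),
                    ecosystem_type = "temperate_woodland")
  rep1 <- qcReport(cd, met, min_sites = 3)
  # permute site order: same retained set
  perm <- sample(nrow(siteTable(cd)))
  cd2 <- communityData(communitySamples(cd), siteTable(cd)[perm, ])
  rep2 <- qcReport(cd2, met[perm, ], min_sites = 3)
  expect_setequal(rep1$retained_density, rep2$retained_density)
  # union of individual rules equals the excluded set, in any order
  lr <- rep1$layer_rules
  ruleCols <- c("rule1_woodland_single_layer", "rule2_scrub_cover_only",
                "rule3_temperate_agri_shallow")
  for (ord in list(ruleCols, rev(ruleCols), ruleCols[c(2, 1, 3)])) {
    manual <- Reduce(`|`, lapply(ord, function(cl) lr[[cl]]))
    expect_equal(manual, lr$excluded)
  }
  expect_equal(unname(rep1$counts["retained"] + rep1$counts["excluded"]),
               unname(rep1$counts["input"]))
})

test_that("deny/allow lists control exclusion of flagged sites", {
  cd <- qcFixture()
  met <- data.frame(site_id = siteTable(cd)$site_id,
                    density = c(100, 5000, 8000, 3000, 4000, 2000),
                    ecosystem_type = "temperate_woodland")
  # flags alone never exclude
  repA <- qcReport(cd, met, min_sites = 3)
  expect_false("low_density_denylist" %in% repA$excluded$reason)
  # deny turns a flag into an exclusion; allow overrides everything
  fl <- suppressWarnings(flagLowDensityOutliers(met, min_sites = 3))
  if (any(fl$flagged)) {
    deny <- fl$site_id[fl$flagged][1]
    repB <- qcReport(cd, met, deny = deny, min_sites = 3)
    expect_true(deny %in% repB$excluded$site_id)
    repC <- qcReport(cd, met, deny = deny, allow = deny, min_sites = 3)
    expect_false(deny %in% repC$excluded$site_id)
  }
})
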