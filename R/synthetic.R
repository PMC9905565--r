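#' Synthetic-dataset generator configuration
#'
#' Defaults encode the study conditions the generator emulates: a few
#' hundred sites spanning -70..70 degrees latitude, a strong latitudinal
#' density gradient on the log10 scale (about 20-fold higher expected
#' density at 70 degrees than at the equator, so tundra greatly exceeds the
#' tropics), 1-20 samples per site with a median near 6, negative-binomial
#' per-sample counts (overdispersion typical of soil fauna), genus body
#' lengths from the packaged 0.2-5 mm trait table, mean annual topsoil
#' temperature falling linearly from 27 C at the equator to -10 C at 70
#' degrees, and habitats drawn per climate band so the nine retained
#' ecosystem types are all populated.
#'
#' @param n_sites number of sites (default 300).
#' @param lat_range latitude span, degrees (default c(-70, 70)).
#' @param density_beta0 log10 expected density (individuals m^-2) at the
#'   equator (default 3.78, about 6000 m^-2).
#' @param density_beta1 increase in log10 density per degree of absolute
#'   latitude (default log10(20)/70: a 20-fold polar:tropical gradient).
#' @param density_sd between-site lognormal noise, log10 units (default
#'   0.4).
#' @param samples_lambda Poisson mean for samples per site, truncated to
#'   [1, 20] (default 6).
#' @param sampling_area_m2 area of one sample core (default 0.0025, a
#'   5 x 5 cm soil core).
#' @param dispersion negative-binomial size parameter for per-sample counts
#'   (default 2).
#' @param richness_beta0 expected site species-pool size at the equator
#'   (default 30).
#' @param richness_beta1 change in pool size per degree absolute latitude
#'   (default -0.15: weakly richer tropics).
#' @param temp_equator,temp_pole70 mean annual topsoil temperature (C) at 0
#'   and 70 degrees (defaults 27 and -10).
#' @param temp_sd site-level temperature noise, C (default 1).
#' @param seed mandatory integer seed.
#' @return named list with class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(n_sites = 300, lat_range = c(-70, 70),
                            density_beta0 = 3.78,
                            density_beta1 = log10(20) / 70,
                            density_sd = 0.4, samples_lambda = 6,
                            sampling_area_m2 = 0.0025, dispersion = 2,
                            richness_beta0 = 30, richness_beta1 = -0.15,
                            temp_equator = 27, temp_pole70 = -10,
                            temp_sd = 1, seed) {
  stopIfNot(!missing(seed) && is.finite(seed), "seed is mandatory")
  stopIfNot(n_sites >= 1, "n_sites must be >= 1")
  cfg <- list(n_sites = n_sites, lat_range = lat_range,
              density_beta0 = density_beta0, density_beta1 = density_beta1,
              density_sd = density_sd, samples_lambda = samples_lambda,
              sampling_area_m2 = sampling_area_m2, dispersion = dispersion,
              richness_beta0 = richness_beta0,
              richness_beta1 = richness_beta1,
              temp_equator = temp_equator, temp_pole70 = temp_pole70,
              temp_sd = temp_sd, seed = as.integer(seed))
  structure(cfg, class = "GeneratorConfig")
}

habitatForBand <- function(band, n) {
  probs <- switch(band,
    polar = c(woodland = 0.15, scrub = 0.60, grassland = 0.25,
              agriculture = 0),
    temperate = c(woodland = 0.45, scrub = 0.10, grassland = 0.25,
                  agriculture = 0.20),
    tropical = c(woodland = 0.65, scrub = 0, grassland = 0,
                 agriculture = 0.35))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Assign synthetic sites to IPBES-style bootstrap regions
#'
#' Coarse longitude/latitude rule mapping coordinates to the four
#' continental reporting regions used as bootstrap strata (Americas; Europe
#' and Central Asia; Africa; Asia-Pacific). Intended for synthetic data, not
#' for real-world geocoding.
#'
#' @param latitude,longitude degrees.
#' @return character vector of region labels.
#' @export
assignRegion <- function(latitude, longitude) {
  ifelse(longitude < -30, "americas",
         ifelse(longitude >= 60, "asia_pacific",
                ifelse(latitude >= 12, "europe_central_asia", "africa")))
}

#' Generate a synthetic community dataset with known ground truth
#'
#' Simulates sites, samples and genus-level counts under the configured
#' latitudinal gradients (see [generatorConfig()]). Each site draws a genus
#' pool from the packaged trait table with lognormal relative-abundance
#' weights; per-sample per-genus counts are negative binomial around
#' \code{expected density x sampling area x weight}, so rare genera produce
#' the singletons and doubletons that drive Chao extrapolation. The returned
#' ground truth makes every downstream estimate checkable: expected and
#' realized site density, the genus pool (true richness), and the generator
#' coefficients.
#'
#' @param config a [generatorConfig()].
#' @return list with \code{data} (a [CommunityData-class]) and \code{truth}
#'   (list: \code{sites} data.frame with \code{true_log10_density},
#'   \code{true_density}, \code{true_richness}, \code{soil_temperature};
#'   \code{coefficients}).
#' @examples
#' gd <- generateDataset(generatorConfig(n_sites = 20, seed = 1))
#' gd$data
#' @export
generateDataset <- function(config) {
  stopIfNot(inherits(config, "GeneratorConfig"), "config must be a GeneratorConfig")
  set.seed(config$seed)
  traits <- defaultTraits()
  n <- config$n_sites
  lat <- stats::runif(n, config$lat_range[1], config$lat_range[2])
  lon <- stats::runif(n, -180, 180)
  band <- as.character(classifyClimateBand(lat))
  habitat <- character(n)
  for (b in unique(band))
    habitat[band == b] <- habitatForBand(b, sum(band == b))
  soilT <- config$temp_equator +
    (config$temp_pole70 - config$temp_equator) * abs(lat) / 70 +
    stats::rnorm(n, 0, config$temp_sd)
  log10Dens <- config$density_beta0 + config$density_beta1 * abs(lat) +
    stats::rnorm(n, 0, config$density_sd)
  poolSize <- pmax(5, pmin(nrow(traits),
    round(config$richness_beta0 + config$richness_beta1 * abs(lat) +
            stats::rnorm(n, 0, 3))))
  nSamp <- pmin(20, pmax(1, stats::rpois(n, config$samples_lambda)))

  siteIds <- sprintf("site%03d", seq_len(n))
  sampleRows <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- sample(traits$genus, poolSize[i])
    w <- stats::rlnorm(poolSize[i], 0, 1.2)
    w <- w / sum(w)
    lambda <- 10^log10Dens[i] * config$sampling_area_m2
    rows <- lapply(seq_len(nSamp[i]), function(j) {
      counts <- stats::rnbinom(poolSize[i], mu = lambda * w,
                               size = config$dispersion)
      keep <- counts > 0
      if (!any(keep)) return(NULL)
      data.frame(site_id = siteIds[i],
                 sample_id = sprintf("%s_s%02d", siteIds[i], j),
                 taxon = pool[keep], abundance = counts[keep],
                 sampling_area = config$sampling_area_m2,
                 sampling_depth = 5, layers = "litter+soil",
                 method = "tullgren", stringsAsFactors = FALSE)
    })
    sampleRows[[i]] <- do.call(rbind, rows)
  }
  samples <- do.call(rbind, sampleRows)
  sites <- data.frame(site_id = siteIds, latitude = lat, longitude = lon,
                      habitat = habitat, soil_temperature = soilT,
                      stringsAsFactors = FALSE)
  # drop sites whose every sample came up empty (possible at low density)
  sites <- sites[sites$site_id %in% samples$site_id, , drop = FALSE]
  truthSites <- data.frame(site_id = siteIds, latitude = lat,
                           true_log10_density = log10Dens,
                           true_density = 10^log10Dens,
                           true_richness = poolSize,
                           soil_temperature = soilT,
                           n_samples = nSamp, stringsAsFactors = FALSE)
  list(data = communityData(samples, sites),
       truth = list(sites = truthSites,
                    coefficients = config[c("density_beta0", "density_beta1",
                                            "density_sd", "richness_beta0",
                                            "richness_beta1")]))
}

#' Write a community dataset to delimited text
#'
#' Emits the long-format CSV dialect that [readCommunityTable()] reads, so
#' generated data can round-trip through ingestion unchanged.
#'
#' @param cd a [CommunityData-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCommunityTable <- function(cd, path) {
  s <- communitySamples(cd)
  st <- siteTable(cd)
  i <- match(s$site_id, st$site_id)
  out <- cbind(s[, c("site_id", "sample_id", "taxon", "abundance",
                     "sampling_area", "sampling_depth", "layers", "method")],
               st[i, c("latitude", "longitude", "habitat",
                       "soil_temperature")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic covariate grid with a known response surface
#'
#' Builds a rectangular latitude/longitude pixel grid whose covariates are
#' noisy functions of absolute latitude (plus pure-noise channels), and a
#' true log10 density surface following the generator's latitudinal model.
#' The true pixel values and the true global total (sum of back-transformed
#' density times pixel area) are returned for recovery tests.
#'
#' @param config a [generatorConfig()] (supplies the density coefficients
#'   and the seed).
#' @param n_lon,n_lat grid dimensions (default 40 x 25; at least 100 pixels
#'   in total).
#' @param n_noise_covariates extra covariates uncorrelated with the signal
#'   (default 4).
#' @param covariate_noise_sd noise on the informative covariates (default
#'   0.2).
#' @param signal \code{"latitudinal"} (default) or \code{"none"} (the true
#'   surface is flat; covariates carry no information about it).
#' @return list with \code{grid} (data.frame: \code{pixel_id}, \code{lat},
#'   \code{lon}, \code{area_m2}, covariates \code{cov1..covK}),
#'   \code{true_log10} (per pixel), \code{true_total} (individuals),
#'   \code{covariates} (names).
#' @export
generateCovariateGrid <- function(config, n_lon = 40, n_lat = 25,
                                  n_noise_covariates = 4,
                                  covariate_noise_sd = 0.2,
                                  signal = c("latitudinal", "none")) {
  signal <- match.arg(signal)
  stopIfNot(n_lon * n_lat >= 100, "need at least 100 pixels")
  set.seed(config$seed + 1000L)
  latSeq <- seq(config$lat_range[1], config$lat_range[2], length.out = n_lat)
  lonSeq <- seq(-180, 180, length.out = n_lon)
  g <- expand.grid(lon = lonSeq, lat = latSeq)
  npix <- nrow(g)
  dlat <- diff(latSeq[1:2])
  dlon <- diff(lonSeq[1:2])
  a <- abs(g$lat) / 70
  # cov2 is exact scaled |lat| so the true latitudinal surface is exactly
  # representable from the covariates (ground-truth recovery is then a
  # property of the pipeline, not of covariate noise); the rest are noisy
  covs <- data.frame(
    cov1 = config$temp_equator +
      (config$temp_pole70 - config$temp_equator) * a +
      stats::rnorm(npix, 0, covariate_noise_sd * 10),
    cov2 = a,
    cov3 = sqrt(a) + stats::rnorm(npix, 0, covariate_noise_sd),
    cov4 = a^2 + stats::rnorm(npix, 0, covariate_noise_sd))
  for (k in seq_len(n_noise_covariates))
    covs[[paste0("cov", 4 + k)]] <- stats::rnorm(npix)
  trueLog10 <- if (signal == "latitudinal")
    config$density_beta0 + config$density_beta1 * abs(g$lat)
  else rep(config$density_beta0, npix)
  grid <- cbind(data.frame(pixel_id = seq_len(npix), lat = g$lat,
                           lon = g$lon,
                           area_m2 = pixelAreaM2(g$lat, dlat, dlon)),
                covs)
  list(grid = grid, true_log10 = trueLog10,
       true_total = sum(10^trueLog10 * grid$area_m2),
       covariates = names(covs))
}

#' Sample training sites from a synthetic grid
#'
#' Draws pixels (without replacement) as training sites and adds
#' observation noise to the true log10 response, plus a bootstrap region
#' label from [assignRegion()].
#'
#' @param gridObj result of [generateCovariateGrid()].
#' @param n_sites number of training sites.
#' @param noise_sd observation noise on the log10 response (default 0.2).
#' @param seed integer seed.
#' @return data.frame of training sites with covariates, \code{response}
#'   (log10 scale), \code{lat}, \code{lon}, \code{region}.
#' @export
sampleTrainingSites <- function(gridObj, n_sites, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  idx <- sample(nrow(gridObj$grid), n_sites)
  tr <- gridObj$grid[idx, , drop = FALSE]
  tr$response <- gridObj$true_log10[idx] + stats::rnorm(n_sites, 0, noise_sd)
  tr$region <- assignRegion(tr$lat, tr$lon)
  rownames(tr) <- NULL
  tr
}
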