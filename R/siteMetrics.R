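#' Site-level community metrics
#'
#' Aggregates trait-attached community samples into per-site density, dry and
#' fresh biomass, community metabolism, and trimmed community-weighted mean
#' body mass and individual metabolic rate.
#'
#' Per sample: density is total individuals divided by sampling area; biomass
#' and metabolism are sums over specimens (abundance times per-individual
#' mass or rate) divided by sampling area; community-weighted means (CWM) are
#' abundance-weighted averages over specimens with genus-level traits.
#' Per site: density, biomass and metabolism are plain means across samples;
#' CWM body mass and CWM metabolic rate are averaged across samples with a
#' symmetric 10\% trim ([trimmedMean()]) to damp outlier samples
#' (\code{trim_level = "specimen"} instead trims the pooled per-specimen
#' distribution of the site). Specimens without genus-level traits
#' contribute to density but not to mass or metabolism; sites where no
#' specimen has traits get \code{NA} for every metric except density, with
#' the reason recorded in the \code{note} column.
#'
#' @param cd a [CommunityData-class] whose sample table carries
#'   \code{body_length_mm} and \code{morphogroup} (see [attachTraits()]).
#' @param allometry an [AllometrySet-class].
#' @param constants [metabolicConstants()].
#' @param variant coefficient variant, \code{"mean"}/\code{"min"}/\code{"max"}
#'   (see [lengthToDryMass()]).
#' @param trim trim fraction for CWM aggregation across samples.
#' @param trim_level \code{"sample"} (default, trim per-sample CWMs) or
#'   \code{"specimen"} (trim the site's pooled specimen-level values).
#' @return data.frame, one row per site: \code{site_id}, \code{n_samples},
#'   \code{density} (individuals m^-2), \code{dry_biomass_mg_m2},
#'   \code{fresh_biomass_mg_m2}, \code{mean_body_mass_ug} (dry),
#'   \code{mean_individual_metabolism_mJ_h},
#'   \code{community_metabolism_J_h_m2}, \code{variant}, \code{note}.
#' @examples
#' f <- system.file("extdata", "community_example.csv",
#'                  package = "springtailMetrics")
#' cd <- attachTraits(readCommunityTable(f, quiet = TRUE))
#' computeSiteMetrics(cd)
#' @export
computeSiteMetrics <- function(cd, allometry = defaultAllometry(),
                               constants = metabolicConstants(),
                               variant = "mean", trim = 0.10,
                               trim_level = c("sample", "specimen")) {
  variant <- checkVariant(variant)
  trim_level <- match.arg(trim_level)
  s <- communitySamples(cd)
  sites <- siteTable(cd)
  stopIfNot(all(c("body_length_mm", "morphogroup") %in% names(s)),
            "sample table lacks traits; run attachTraits() first")

  hasTrait <- !is.na(s$body_length_mm) & !is.na(s$morphogroup)
  s$dry_ug <- NA_real_
  s$fresh_ug <- NA_real_
  if (any(hasTrait)) {
    s$dry_ug[hasTrait] <- lengthToDryMass(s$body_length_mm[hasTrait],
                                          s$morphogroup[hasTrait],
                                          allometry, variant)
    s$fresh_ug[hasTrait] <- dryToFreshMass(s$dry_ug[hasTrait],
                                           s$morphogroup[hasTrait],
                                           allometry, variant)
  }
  tempK <- celsiusToKelvin(sites$soil_temperature[match(s$site_id,
                                                        sites$site_id)])
  s$rate_J_h <- NA_real_
  okRate <- hasTrait & !is.na(tempK) & s$fresh_ug > 0
  s$rate_J_h[okRate] <- individualMetabolicRate(s$fresh_ug[okRate] / 1000,
                                                tempK[okRate], constants)

  out <- lapply(split(s, s$site_id), function(ss) {
    bySample <- split(ss, ss$sample_id)
    dens <- vapply(bySample, function(g)
      sum(g$abundance) / g$sampling_area[1], numeric(1))
    tr <- lapply(bySample, function(g) g[!is.na(g$dry_ug), , drop = FALSE])
    nTr <- vapply(tr, nrow, integer(1))
    anyTraits <- any(nTr > 0)
    perArea <- function(g, col)
      if (nrow(g)) sum(g$abundance * g[[col]]) / g$sampling_area[1] else NA_real_
    cwm <- function(g, col)
      if (nrow(g) && sum(g$abundance) > 0)
        sum(g$abundance * g[[col]]) / sum(g$abundance) else NA_real_

    if (anyTraits) {
      dry <- mean(vapply(tr, perArea, numeric(1), col = "dry_ug"),
                  na.rm = TRUE) / 1000   # ug -> mg per m2
      fresh <- mean(vapply(tr, perArea, numeric(1), col = "fresh_ug"),
                    na.rm = TRUE) / 1000
      haveRate <- any(vapply(tr, function(g) any(!is.na(g$rate_J_h)),
                             logical(1)))
      metab <- if (haveRate)
        mean(vapply(tr, perArea, numeric(1), col = "rate_J_h"),
             na.rm = TRUE) else NA_real_
      if (trim_level == "sample") {
        cwmMass <- trimmedMean(vapply(tr, cwm, numeric(1), col = "dry_ug"),
                               trim)
        cwmRate <- if (haveRate)
          trimmedMean(vapply(tr, cwm, numeric(1), col = "rate_J_h"),
                      trim) * 1000 else NA_real_
      } else {
        pooled <- do.call(rbind, tr)
        massRep <- rep(pooled$dry_ug, times = round(pooled$abundance))
        cwmMass <- trimmedMean(massRep, trim)
        cwmRate <- if (haveRate)
          trimmedMean(rep(pooled$rate_J_h, times = round(pooled$abundance)),
                      trim) * 1000 else NA_real_
      }
      note <- NA_character_
    } else {
      dry <- fresh <- metab <- cwmMass <- cwmRate <- NA_real_
      note <- "no genus-level traits: only density estimated"
    }
    data.frame(site_id = ss$site_id[1], n_samples = length(bySample),
               density = mean(dens), dry_biomass_mg_m2 = dry,
               fresh_biomass_mg_m2 = fresh, mean_body_mass_ug = cwmMass,
               mean_individual_metabolism_mJ_h = cwmRate,
               community_metabolism_J_h_m2 = metab,
               variant = variant, note = note, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  i <- match(res$site_id, sites$site_id)
  res$latitude <- sites$latitude[i]
  res$longitude <- sites$longitude[i]
  res$habitat <- sites$habitat[i]
  res$soil_temperature <- sites$soil_temperature[i]
  res$climate_band <- as.character(classifyClimateBand(res$latitude))
  res$ecosystem_type <- ecosystemType(res$climate_band, res$habitat)$ecosystem_type
  res
}
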