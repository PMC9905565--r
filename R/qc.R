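#' Layer-based technical selection rules
#'
#' Applies the documented technical exclusion rules for unreliable density
#' estimates, each evaluated independently (exclusion is their union):
#' \enumerate{
#'   \item woodlands where only soil or only litter was sampled;
#'   \item scrub where only ground cover (litter/mosses) was sampled;
#'   \item temperate agricultural sites where only soil shallower than 10 cm
#'     was sampled.
#' }
#' Sites whose samples carry no layer metadata cannot be evaluated and are
#' flagged \code{unevaluated} rather than excluded.
#'
#' @param cd a [CommunityData-class].
#' @return data.frame per site: \code{site_id}, logical columns
#'   \code{rule1_woodland_single_layer}, \code{rule2_scrub_cover_only},
#'   \code{rule3_temperate_agri_shallow}, \code{unevaluated},
#'   \code{excluded}.
#' @export
applyLayerRules <- function(cd) {
  s <- communitySamples(cd)
  sites <- siteTable(cd)
  out <- lapply(seq_len(nrow(sites)), function(i) {
    id <- sites$site_id[i]
    ss <- s[s$site_id == id, , drop = FALSE]
    lay <- unique(unlist(splitLayers(ss$layers)))
    lay <- lay[!is.na(lay)]
    if (!length(lay)) {
      return(data.frame(site_id = id, rule1_woodland_single_layer = FALSE,
                        rule2_scrub_cover_only = FALSE,
                        rule3_temperate_agri_shallow = FALSE,
                        unevaluated = TRUE, excluded = FALSE))
    }
    hab <- sites$habitat[i]
    band <- as.character(classifyClimateBand(sites$latitude[i]))
    soilOnly <- setequal(lay, "soil")
    litterOnly <- setequal(lay, "litter")
    coverOnly <- length(setdiff(lay, c("litter", "other_cover"))) == 0
    depth <- suppressWarnings(max(ss$sampling_depth, na.rm = TRUE))
    r1 <- hab == "woodland" && (soilOnly || litterOnly)
    r2 <- hab == "scrub" && coverOnly
    r3 <- hab == "agriculture" && band == "temperate" && soilOnly &&
      is.finite(depth) && depth < 10
    data.frame(site_id = id, rule1_woodland_single_layer = r1,
               rule2_scrub_cover_only = r2,
               rule3_temperate_agri_shallow = r3,
               unevaluated = FALSE, excluded = r1 || r2 || r3)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag unrealistically low density outliers
#'
#' Within each ecosystem type, flags sites that are both in the lowest 10\%
#' of densities and more than three times below the type's 1st percentile
#' (type-7 linear-interpolation quantile). This mirrors a semi-manual check:
#' flagged sites are candidates for exclusion, which remains an explicit,
#' separate step (see the \code{deny} argument of [qcReport()]).
#'
#' @param metrics data.frame with \code{site_id}, \code{density},
#'   \code{ecosystem_type} (e.g. from [computeSiteMetrics()]).
#' @param min_sites minimum sites per ecosystem type needed to estimate the
#'   percentile (default 20); smaller types yield no flags and a warning.
#' @return data.frame with \code{site_id}, \code{ecosystem_type},
#'   \code{density}, \code{flagged}.
#' @export
flagLowDensityOutliers <- function(metrics, min_sites = 20) {
  need <- c("site_id", "density", "ecosystem_type")
  stopIfNot(all(need %in% names(metrics)),
            "metrics needs site_id, density, ecosystem_type")
  res <- lapply(split(metrics, metrics$ecosystem_type), function(g) {
    g <- g[is.finite(g$density), , drop = FALSE]
    flagged <- rep(FALSE, nrow(g))
    if (nrow(g) >= min_sites) {
      q01 <- stats::quantile(g$density, 0.01, type = 7, names = FALSE)
      q10 <- stats::quantile(g$density, 0.10, type = 7, names = FALSE)
      flagged <- g$density <= q10 & g$density < q01 / 3
    } else if (nrow(g) > 0) {
      warning(sprintf("ecosystem type '%s' has %d < %d sites: no outlier flags",
                      g$ecosystem_type[1], nrow(g), min_sites), call. = FALSE)
    }
    data.frame(site_id = g$site_id, ecosystem_type = g$ecosystem_type,
               density = g$density, flagged = flagged)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Richness-estimate eligibility
#'
#' Retains sites with at least \code{min_samples} samples and
#' (morpho)species-level identification for extrapolated richness; pooled
#' sites are handled separately by the completeness model
#' ([predictPooledRichness()]). Ineligible sites remain valid for density.
#'
#' @param sites data.frame with \code{site_id}, \code{n_samples} and
#'   \code{id_level} (\code{"species"}, \code{"morphospecies"} or
#'   \code{"genus"}).
#' @param min_samples minimum sample count (default 3).
#' @return input with a logical \code{richness_eligible} column.
#' @export
richnessEligibility <- function(sites, min_samples = 3) {
  need <- c("site_id", "n_samples", "id_level")
  stopIfNot(all(need %in% names(sites)),
            "sites needs site_id, n_samples, id_level")
  sites$richness_eligible <- sites$n_samples >= min_samples &
    sites$id_level %in% c("species", "morphospecies")
  sites
}

#' Combined QC report
#'
#' Runs the layer rules and the low-density flags and reconciles them into a
#' per-metric retained-site report. Low-density flags only exclude a site if
#' it appears in \code{deny} (the explicit counterpart of a manual check);
#' \code{allow} overrides any exclusion.
#'
#' @param cd a [CommunityData-class].
#' @param metrics output of [computeSiteMetrics()].
#' @param deny,allow character vectors of site ids.
#' @param min_sites passed to [flagLowDensityOutliers()].
#' @return list with \code{layer_rules}, \code{density_flags},
#'   \code{retained_density} (site ids), \code{excluded} (data.frame of
#'   site_id + reason), and \code{counts}.
#' @export
qcReport <- function(cd, metrics, deny = character(), allow = character(),
                     min_sites = 20) {
  lr <- applyLayerRules(cd)
  fl <- suppressWarnings(flagLowDensityOutliers(metrics, min_sites))
  lowIds <- fl$site_id[fl$flagged & fl$site_id %in% deny]
  excl <- rbind(
    data.frame(site_id = lr$site_id[lr$excluded],
               reason = rep("layer_rule", sum(lr$excluded))),
    data.frame(site_id = lowIds,
               reason = rep("low_density_denylist", length(lowIds))))
  excl <- excl[!excl$site_id %in% allow, , drop = FALSE]
  retained <- setdiff(siteTable(cd)$site_id, excl$site_id)
  list(layer_rules = lr, density_flags = fl, retained_density = retained,
       excluded = excl,
       counts = c(input = nrow(siteTable(cd)),
                  excluded = length(unique(excl$site_id)),
                  retained = length(retained)))
}
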