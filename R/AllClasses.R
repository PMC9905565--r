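#' @import methods
NULL

HABITAT_LEVELS <- c("woodland", "scrub", "grassland", "agriculture", "other")
CLIMATE_BANDS <- c("polar", "temperate", "tropical")
LAYER_LEVELS <- c("litter", "soil", "other_cover")

# Ecosystem types with enough sites worldwide to support cross-type comparison;
# all other band x habitat pairs are reported but flagged as not retained.
RETAINED_ECOSYSTEM_TYPES <- c(
  "polar_scrub", "polar_grassland", "polar_woodland",
  "temperate_woodland", "temperate_scrub", "temperate_grassland",
  "temperate_agriculture", "tropical_agriculture", "tropical_woodland"
)

SAMPLE_COLUMNS <- c("site_id", "sample_id", "taxon", "abundance",
                    "sampling_area", "sampling_depth", "layers", "method")
SITE_COLUMNS <- c("site_id", "latitude", "longitude", "habitat",
                  "soil_temperature")

#' Community samples with site metadata
#'
#' Container for one harmonized community dataset: a long-format sample table
#' (one row per sample x taxon), a per-site metadata table, and the rows
#' rejected during ingestion. The sample table is the pipeline's atomic input;
#' every downstream metric is computed from it.
#'
#' @slot samples data.frame with columns \code{site_id}, \code{sample_id},
#'   \code{taxon}, \code{abundance} (individuals per sample, >= 0),
#'   \code{sampling_area} (m^2, > 0), \code{sampling_depth} (cm),
#'   \code{layers} (\code{"+"}-separated subset of litter/soil/other_cover)
#'   and \code{method}. Optional columns (e.g. \code{genus}) are preserved.
#' @slot sites data.frame with columns \code{site_id}, \code{latitude},
#'   \code{longitude}, \code{habitat} (woodland/scrub/grassland/agriculture/
#'   other) and \code{soil_temperature} (mean annual topsoil temperature,
#'   degrees C).
#' @slot rejected data.frame of input rows that failed validation, with a
#'   \code{reason} column.
#'
#' @seealso [communityData()], [readCommunityTable()], [generateDataset()]
#' @export
setClass("CommunityData",
  slots = c(samples = "data.frame", sites = "data.frame",
            rejected = "data.frame"))

setValidity("CommunityData", function(object) {
  msg <- character()
  s <- object@samples
  miss <- setdiff(c("site_id", "sample_id", "taxon", "abundance",
                    "sampling_area"), names(s))
  if (length(miss))
    msg <- c(msg, paste("samples missing columns:", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (!is.numeric(s$abundance) || any(!is.finite(s$abundance)) ||
        any(s$abundance < 0))
      msg <- c(msg, "abundance must be finite and >= 0")
    if (!is.numeric(s$sampling_area) || any(!is.finite(s$sampling_area)) ||
        any(s$sampling_area <= 0))
      msg <- c(msg, "sampling_area must be finite and > 0")
  }
  st <- object@sites
  miss <- setdiff(c("site_id", "latitude", "longitude", "habitat"), names(st))
  if (length(miss))
    msg <- c(msg, paste("sites missing columns:", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (anyDuplicated(st$site_id))
      msg <- c(msg, "duplicated site_id in site table")
    if (any(abs(st$latitude) > 90, na.rm = TRUE))
      msg <- c(msg, "latitude outside [-90, 90]")
    if (any(abs(st$longitude) > 180, na.rm = TRUE))
      msg <- c(msg, "longitude outside [-180, 180]")
    bad <- setdiff(unique(st$habitat), HABITAT_LEVELS)
    if (length(bad))
      msg <- c(msg, paste("unknown habitat:", paste(bad, collapse = ", ")))
    orphan <- setdiff(unique(s$site_id), st$site_id)
    if (length(orphan))
      msg <- c(msg, paste0(length(orphan), " sample site_id(s) missing from site table"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityData object
#'
#' @param samples data.frame of sample x taxon rows (see
#'   [CommunityData-class]).
#' @param sites data.frame of site metadata.
#' @param rejected optional data.frame of rejected input rows.
#' @return A validated [CommunityData-class] object.
#' @examples
#' cd <- communityData(
#'   samples = data.frame(site_id = "s1", sample_id = "s1_1",
#'                        taxon = "Folsomia", abundance = 10,
#'                        sampling_area = 0.0025),
#'   sites = data.frame(site_id = "s1", latitude = 52, longitude = 10,
#'                      habitat = "woodland", soil_temperature = 8))
#' cd
#' @export
communityData <- function(samples, sites, rejected = NULL) {
  if (is.null(rejected))
    rejected <- data.frame(row = integer(), reason = character())
  samples <- as.data.frame(samples)
  sites <- as.data.frame(sites)
  if (!"soil_temperature" %in% names(sites)) sites$soil_temperature <- NA_real_
  new("CommunityData", samples = samples, sites = sites,
      rejected = as.data.frame(rejected))
}

#' @describeIn CommunityData-class sample table accessor
#' @param x,object a \code{CommunityData} object
#' @export
communitySamples <- function(x) x@samples

#' @describeIn CommunityData-class site table accessor
#' @export
siteTable <- function(x) x@sites

#' @describeIn CommunityData-class rejected-row accessor
#' @export
rejectedRows <- function(x) x@rejected

#' @describeIn CommunityData-class number of sites
#' @export
nSites <- function(x) nrow(x@sites)

setMethod("show", "CommunityData", function(object) {
  cat("CommunityData:", nrow(object@samples), "sample x taxon rows,",
      length(unique(object@samples$sample_id)), "samples,",
      nrow(object@sites), "sites\n")
  if (nrow(object@rejected))
    cat("  rejected rows:", nrow(object@rejected), "\n")
  hab <- table(object@sites$habitat)
  cat("  habitats:", paste(names(hab), hab, sep = ":", collapse = " "), "\n")
})

#' Group-specific length-mass allometry coefficients
#'
#' Holds one log10-log10 length-to-dry-mass regression per row,
#' \code{log10(mass_ug) = intercept + slope * log10(length_mm)}, with standard
#' errors, plus a multiplicative dry-to-fresh conversion factor per
#' morphogroup. Several rows may share a morphogroup; their back-transformed
#' predictions are averaged.
#'
#' @slot table data.frame with columns \code{group}, \code{intercept},
#'   \code{intercept_se}, \code{slope}, \code{slope_se},
#'   \code{dry_fresh_factor}, \code{dry_fresh_se}.
#' @seealso [allometrySet()], [readAllometry()], [lengthToDryMass()]
#' @export
setClass("AllometrySet", slots = c(table = "data.frame"))

setValidity("AllometrySet", function(object) {
  tb <- object@table
  need <- c("group", "intercept", "intercept_se", "slope", "slope_se",
            "dry_fresh_factor", "dry_fresh_se")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  msg <- character()
  if (any(tb$slope <= 0)) msg <- c(msg, "slope must be > 0")
  if (any(tb$dry_fresh_factor <= 1))
    msg <- c(msg, "dry_fresh_factor must be > 1 (fresh mass exceeds dry mass)")
  if (any(tb$intercept_se < 0) || any(tb$slope_se < 0) || any(tb$dry_fresh_se < 0))
    msg <- c(msg, "standard errors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AllometrySet
#'
#' @param table data.frame of regression rows (see [AllometrySet-class]).
#' @return An \code{AllometrySet}.
#' @export
allometrySet <- function(table) {
  new("AllometrySet", table = as.data.frame(table))
}

#' @describeIn AllometrySet-class coefficient table accessor
#' @param x,object an \code{AllometrySet}
#' @export
allometryTable <- function(x) x@table

#' @describeIn AllometrySet-class morphogroup names
#' @export
allometryGroups <- function(x) unique(x@table$group)

setMethod("show", "AllometrySet", function(object) {
  cat("AllometrySet:", nrow(object@table), "regressions for",
      length(unique(object@table$group)), "morphogroups\n")
  cat("  groups:", paste(unique(object@table$group), collapse = ", "), "\n")
})

#' Read an allometry coefficient table
#'
#' Reads a delimited text file with the columns documented in
#' [AllometrySet-class]. The file shipped under
#' \code{inst/extdata/allometry_synthetic.tsv} carries synthetic placeholder
#' coefficients of realistic magnitude; published coefficient tables can be
#' dropped in using the same format.
#'
#' @param path file path; comma- or tab-delimited, header required.
#' @return An [AllometrySet-class].
#' @export
readAllometry <- function(path) {
  tb <- utils::read.delim(path, sep = guessDelim(path),
                          stringsAsFactors = FALSE)
  allometrySet(tb)
}

#' Default allometry coefficients
#'
#' Synthetic placeholder coefficient set shipped with the package (four
#' morphogroups spanning the main springtail body plans). Values are of
#' realistic magnitude for collembolan length-mass regressions but are not
#' the published supplementary coefficients.
#'
#' @return An [AllometrySet-class].
#' @examples
#' defaultAllometry()
#' @export
defaultAllometry <- function() {
  readAllometry(system.file("extdata", "allometry_synthetic.tsv",
                            package = "springtailMetrics", mustWork = TRUE))
}
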